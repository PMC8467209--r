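test_that("scene truth matches closed-form band areas", {
  # everything sky
  sky <- generate_scene(scene_spec(width = 128, sky_lat = -pi / 2 + 1e-6,
                                   road_lat = -pi / 2), seed = 1)
  expect_equal(unname(sky$truth["sky"]), 1)

  # sky band [30 deg, 90 deg] covers (sin 90 - sin 30)/2 = 25%
  # half-pixel discretization of the band boundary bounds the error
  sc <- generate_scene(scene_spec(width = 512, sky_lat = pi / 6,
                                  road_lat = -pi / 2), seed = 1)
  expect_lt(abs(sc$truth["sky"] - 0.25), 0.005)

  # default bands: road ~40%, sky ~18.75% of the sphere
  d <- generate_scene(scene_spec(width = 512), seed = 2)
  expect_lt(abs(d$truth["road"] - 0.40), 0.005)
  expect_lt(abs(d$truth["sky"] - 0.1875), 0.005)
})

test_that("scene generation is deterministic under a seed", {
  spec <- synthetic_scene_specs(n = 1, width = 128, seed = 5)[[1]]
  a <- generate_scene(spec, seed = 9)
  b <- generate_scene(spec, seed = 9)
  expect_identical(a$rgb$values, b$rgb$values)
  expect_identical(a$labels$values, b$labels$values)
})

test_that("auditing generated scenes reproduces truth proportions", {
  specs <- synthetic_scene_specs(n = 5, width = 512, seed = 17)
  for (i in seq_along(specs)) {
    sc <- generate_scene(specs[[i]], seed = 100 + i)
    au <- audit_scene(sc$labels, sc$rgb, specs[[i]]$street_scale,
                      out_width = 1024)
    el <- au[au$layer == "constituent_elements", ]
    for (cat in names(sc$truth)) {
      got <- el[[paste0("pland_", cat)]]
      expect_equal(got, 100 * unname(sc$truth[cat]), tolerance = 1,
                   info = paste("scene", i, cat))
    }
  }
})

test_that("audited synthetic scene sets span study-like indicator ranges", {
  ex <- get_test_audits()
  el <- ex$audits[ex$audits$layer == "constituent_elements", ]
  expect_equal(mean(el$pland_road), 40, tolerance = 0.1)
  expect_equal(mean(el$pland_sky), 19, tolerance = 0.2)
  expect_gt(sd(el$pland_plant), 3)
  expect_true(all(el$division >= 0 & el$division < 1))
  expect_true(all(el$shdi >= 0 & el$shdi <= log(4)))
  expect_setequal(unique(el$street_scale), c("small", "medium", "large"))
})

test_that("cohort generation is deterministic and range safe", {
  ex <- get_test_audits()
  r1 <- generate_cohort(ex$audits, effect_config(), seed = 3)
  r2 <- generate_cohort(ex$audits, effect_config(), seed = 3)
  expect_identical(r1, r2)
  r3 <- generate_cohort(ex$audits, effect_config(), seed = 4)
  expect_false(identical(r1$HR.Avg, r3$HR.Avg))

  # ~10k draws: every record satisfies the indicator invariants
  big <- generate_cohort(ex$audits,
                         effect_config(participants = 840,
                                       scenes_per_participant = 12),
                         seed = 6)
  expect_gt(nrow(big), 10000)
  for (cc in EEG_INDICATORS) {
    x <- big[[cc]]
    expect_true(all(x > 0 & x < 1, na.rm = TRUE))
  }
  expect_true(all(big$SCR.n >= 0 & big$SCR.n %% 1 == 0, na.rm = TRUE))
  expect_true(all(big$SCR.Amp >= 0, na.rm = TRUE))
  expect_true(all(big$HR.Avg > 0, na.rm = TRUE))
  for (cc in EVA_INDICATORS)
    expect_true(all(big[[cc]] %in% 1:3 | is.na(big[[cc]])))
  expect_true(all(big$gender %in% 0:1))
})

test_that("cohort geometry and missingness mirror the study footprint", {
  ex <- get_test_audits()
  resp <- generate_cohort(ex$audits, effect_config(), seed = 8)
  expect_equal(nrow(resp), 26 * 12)
  expect_equal(length(unique(resp$participant_id)), 26)
  # EEG block loses about a third of records, HR almost none
  # (binomial noise at n = 312: allow ~3 SD around the 1/3 rate)
  expect_lt(abs(mean(is.na(resp$EEG.En)) - 1 / 3), 0.09)
  expect_lt(mean(is.na(resp$HR.Avg)), 0.05)
  # SCR.n and SCR.Amp are missing together (device-level dropout)
  expect_identical(is.na(resp$SCR.n), is.na(resp$SCR.Amp))
})

test_that("null cohort has intercept-driven EVA frequencies and no exposure link", {
  ex <- get_test_audits()
  cfg <- effect_config(participants = 200)
  resp <- null_cohort(ex$audits, cfg, seed = 11)
  # comfort intercepts encode frequencies (0.30, 0.40, 0.30)
  freq <- as.vector(table(resp$EVA.Co)) / sum(!is.na(resp$EVA.Co))
  expect_lt(max(abs(freq - c(0.30, 0.40, 0.30))), 0.04)

  md <- assemble_model_data(ex$audits, resp, "constituent_elements")
  expect_lt(abs(cor(md$HR.Avg, md$pland_plant, use = "complete.obs")),
            0.05)
})

test_that("a positive SHDI effect raises high comfort across SHDI tertiles", {
  ex <- get_test_audits()
  cfg <- effect_config(
    participants = 300,
    effects = list(EVA.Co = list(
      beta = rbind(`2` = c(pland_plant = 0, pland_sky = 0, pland_road = 0,
                           division = 0, shdi = 2),
                   `3` = c(pland_plant = 0, pland_sky = 0, pland_road = 0,
                           division = 0, shdi = 6)))))
  resp <- generate_cohort(ex$audits, cfg, seed = 13)
  md <- assemble_model_data(ex$audits, resp, "constituent_elements")
  tert <- cut(md$shdi, quantile(md$shdi, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = 1:3)
  p3 <- tapply(md$EVA.Co == 3, tert, mean, na.rm = TRUE)
  expect_true(all(diff(p3) > 0))
})
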