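test_that("group_labels maps ids, preserves counts, rejects unmapped ids", {
  m <- matrix(c(2L, 4L, 4L, 7L), 2, 2)
  r <- spherical_raster(m, geometry = "planar")
  scheme <- class_scheme(list(plant = c(2, 4), sky = 7), other = NULL)
  g <- group_labels(r, scheme)
  expect_identical(g$categories, c("plant", "sky"))
  expect_equal(sum(g$values == 1L), 3)
  expect_equal(sum(g$values == 2L), 1)

  # identity scheme leaves the raster unchanged (up to recoding)
  idt <- class_scheme(list(`2` = 2, `4` = 4, `7` = 7), other = NULL)
  gi <- group_labels(r, idt)
  expect_equal(as.vector(table(gi$values)), as.vector(table(m)))

  strict <- class_scheme(list(plant = 2), other = NULL)
  expect_error(group_labels(r, strict), "unmapped raw ids.*4")

  # with a fall-through category nothing errors and counts are total
  loose <- class_scheme(list(plant = 2))
  gl <- group_labels(r, loose)
  expect_equal(sum(gl$values == match("other", gl$categories)), 3)
})

test_that("pland is an exact pixel ratio", {
  m <- matrix(1L, 3, 4); m[1, 1:3] <- 2L
  r <- spherical_raster(m, geometry = "planar")
  expect_equal(pland(r, "2"), 25)
  expect_equal(pland(r, "1"), 75)
  expect_equal(pland(r, "9"), 0)

  uni <- spherical_raster(matrix(5L, 4, 4), geometry = "planar")
  expect_equal(pland(uni, "5"), 100)

  for (seed in 1:10) {
    r <- random_label_raster(16, 4, seed)
    for (code in 1:4)
      expect_equal(pland(r, as.character(code)),
                   brute_pland(r$values, code))
  }
})

test_that("patch labeling matches the flood-fill oracle", {
  for (seed in 1:50) {
    r <- random_label_raster(16, 3, seed)
    for (conn in c(4, 8)) {
      got <- label_patches(r, conn)
      want <- brute_patch_table(r$values, connectivity = conn)
      expect_equal(nrow(got), nrow(want))
      expect_equal(sort(got$area), sort(want$area))
      expect_equal(sum(got$area), 16 * 16)
    }
  }
})

test_that("checkerboard connectivity: 4 patches rook, 2 patches queen", {
  m <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  r <- spherical_raster(m, geometry = "planar")
  expect_equal(nrow(label_patches(r, 4)), 4)
  expect_equal(nrow(label_patches(r, 8)), 2)
  expect_equal(division(r, 4), 0.75)
  expect_equal(division(r, 8), 0.5)
})

test_that("division closed forms and bounds hold", {
  uni <- spherical_raster(matrix(1L, 4, 4), geometry = "planar")
  expect_equal(division(uni), 0)

  two <- spherical_raster(matrix(rep(c(1L, 2L), each = 8), 4, 4),
                          geometry = "planar")
  expect_equal(division(two), 0.5)

  four <- spherical_raster(rbind(cbind(matrix(1L, 2, 2), matrix(2L, 2, 2)),
                                 cbind(matrix(3L, 2, 2), matrix(4L, 2, 2))),
                           geometry = "planar")
  expect_equal(division(four), 0.75)

  for (seed in 1:20) {
    r <- random_label_raster(12, 3, seed)
    d <- division(r)
    expect_gte(d, 0); expect_lt(d, 1)
  }
})

test_that("shdi closed forms, bounds, and oracle equivalence hold", {
  uni <- spherical_raster(matrix(1L, 4, 4), geometry = "planar")
  expect_equal(shdi(uni), 0)

  two <- spherical_raster(matrix(rep(c(1L, 2L), each = 8), 4, 4),
                          geometry = "planar")
  expect_equal(shdi(two), log(2))

  # proportions (0.7, 0.3)
  m <- matrix(1L, 10, 10); m[1:30] <- 2L
  r <- spherical_raster(m, geometry = "planar")
  expect_equal(shdi(r), -(0.7 * log(0.7) + 0.3 * log(0.3)))
  expect_equal(shdi(r), 0.6108643, tolerance = 1e-6)

  for (seed in 1:20) {
    r <- random_label_raster(12, 4, seed)
    s <- shdi(r)
    m_present <- length(unique(as.vector(r$values)))
    expect_gte(s, 0); expect_lte(s, log(m_present) + 1e-12)
    expect_equal(s, brute_shdi(r$values), tolerance = 1e-12)
    expect_equal(division(r), brute_division(r$values), tolerance = 1e-12)
  }
})

test_that("splitting a patch increases DIVISION; merging classes decreases SHDI", {
  # one 4-pixel patch of class 2 in a class-1 field ...
  m1 <- matrix(1L, 6, 6); m1[3, 2:5] <- 2L
  # ... split into two 2-pixel patches of the same total area
  m2 <- matrix(1L, 6, 6); m2[3, c(1, 2, 5, 6)] <- 2L
  r1 <- spherical_raster(m1, geometry = "planar")
  r2 <- spherical_raster(m2, geometry = "planar")
  expect_gt(division(r2), division(r1))

  for (seed in 1:10) {
    r <- random_label_raster(12, 4, seed)
    merged <- r
    merged$values[merged$values == 2L] <- 1L
    if (length(unique(as.vector(r$values))) >
        length(unique(as.vector(merged$values))))
      expect_lt(shdi(merged), shdi(r))
  }
})

test_that("audit_scene conserves PLAND, tags layers, handles degenerate scenes", {
  ex <- make_test_audits(n_scenes = 2, width = 128, seed = 3)
  a <- ex$audits
  for (i in seq_len(nrow(a))) {
    pl <- unlist(a[i, grep("^pland_", names(a))])
    expect_equal(sum(pl, na.rm = TRUE), 100, tolerance = 1e-9)
  }
  expect_setequal(a$layer, c("constituent_elements", "colors"))

  # a single-category scene has zero fragmentation and diversity
  sky_only <- generate_scene(scene_spec(width = 128,
                                        sky_lat = -pi / 2 + 1e-6,
                                        road_lat = -pi / 2),
                             seed = 1)
  au <- audit_scene(sky_only$labels, sky_only$rgb, "small",
                    out_width = 128)
  el <- au[au$layer == "constituent_elements", ]
  expect_equal(el$division, 0)
  expect_equal(el$shdi, 0)
  expect_equal(el$pland_sky, 100)

  # swapping the rasters swaps the layer contents
  sw <- audit_scene(sky_only$labels, sky_only$labels, "small",
                    out_width = 128)
  expect_equal(sw$division[1], sw$division[2])
})

test_that("re-auditing the same scene is idempotent", {
  sc <- generate_scene(scene_spec(width = 128), seed = 5)
  a1 <- audit_scene(sc$labels, sc$rgb, "large", out_width = 128)
  a2 <- audit_scene(sc$labels, sc$rgb, "large", out_width = 128)
  expect_identical(a1, a2)
})

test_that("class scheme YAML round trip preserves the grouping", {
  scheme <- class_scheme(list(plant = c(4, 9, 17), sky = 2,
                              road = c(6, 11)))
  path <- tempfile(fileext = ".yaml")
  write_class_scheme(scheme, path)
  s2 <- read_class_scheme(path)
  expect_identical(s2$categories, scheme$categories)
  expect_identical(lapply(s2$mapping, as.integer),
                   lapply(scheme$mapping, as.integer))
})
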