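#' Element categories and prototype colors used by the scene generator
#' @keywords internal
SCENE_CATEGORIES <- c("sky", "road", "building", "plant")

# prototype RGB per paintable surface; each classifies to the intended
# color class under default_color_rules() with margin for +-6 noise
SCENE_PROTOTYPES <- list(
  sky = c(90, 140, 230),        # blue
  road = c(120, 120, 120),      # gray
  plant = c(70, 150, 70),       # green
  building_gray = c(160, 160, 160),
  building_white = c(240, 240, 240),
  building_red = c(190, 80, 70)
)

#' Specification of a procedural panoramic street scene
#'
#' The generator tiles the sphere with a sky band (`lat >= sky_lat`), a
#' road band (`lat <= road_lat`), and building facades in between, then
#' paints plant disks (angular-radius spherical caps) on top.  Facades are
#' split into longitude blocks with alternating gray/white/red prototype
#' colors so the color layer has variance and fragmentation of its own.
#'
#' @param width equirectangular raster width in pixels (height = width/2)
#' @param sky_lat lower latitude of the sky band (radians)
#' @param road_lat upper latitude of the road band (radians)
#' @param plant_blobs data.frame with `lon`, `lat`, `radius` (radians)
#' @param building_blocks data.frame with `lon_min`, `lon_max`, `color`
#'   (one of `"gray"`, `"white"`, `"red"`)
#' @param street_scale `"small"`, `"medium"` or `"large"`
#' @param noise_sd half-width of the uniform per-channel RGB jitter
#' @param scene_id identifier
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(width = 1024,
                       sky_lat = asin(1 - 2 * 0.1875),
                       road_lat = asin(2 * 0.40 - 1),
                       plant_blobs = NULL,
                       building_blocks = NULL,
                       street_scale = "medium",
                       noise_sd = 6,
                       scene_id = "scene") {
  stopifnot(width %% 2 == 0, sky_lat > road_lat)
  if (is.null(plant_blobs))
    plant_blobs <- data.frame(lon = numeric(), lat = numeric(),
                              radius = numeric())
  if (is.null(building_blocks))
    building_blocks <- data.frame(lon_min = -pi, lon_max = pi,
                                  color = "gray",
                                  stringsAsFactors = FALSE)
  if (!all(building_blocks$color %in% c("gray", "white", "red")))
    stop("building block colors must be gray, white or red")
  structure(list(width = as.integer(width), sky_lat = sky_lat,
                 road_lat = road_lat, plant_blobs = plant_blobs,
                 building_blocks = building_blocks,
                 street_scale = street_scale, noise_sd = noise_sd,
                 scene_id = scene_id),
            class = "scene_spec")
}

#' Render a procedural street scene
#'
#' Produces the aligned equirectangular RGB panorama and element-category
#' label raster of a [scene_spec()], plus ground-truth solid-angle
#' proportions of the element categories.  Band proportions have the
#' closed form `(sin(lat2) - sin(lat1)) / 2`; with plant disks painted on
#' top the truth is evaluated numerically by cosine-weighting the label
#' raster, the exact relative solid angle of equirectangular pixels.
#'
#' @param spec a `scene_spec`
#' @param seed RNG seed for the color jitter (the geometry is
#'   deterministic given the spec)
#' @return list with `rgb` and `labels` (`spherical_raster`s), `truth`
#'   (named proportions), and `spec`
#' @export
generate_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  W <- spec$width; H <- W %/% 2L
  cen <- equirect_centers(W, H)
  lat <- matrix(cen$lat, H, W)
  lon <- matrix(cen$lon, H, W, byrow = TRUE)

  lab <- matrix(match("building", SCENE_CATEGORIES), H, W)
  lab[lat >= spec$sky_lat] <- match("sky", SCENE_CATEGORIES)
  lab[lat <= spec$road_lat] <- match("road", SCENE_CATEGORIES)

  # facade color block id, used only for the RGB layer
  block <- matrix(1L, H, W)
  bb <- spec$building_blocks
  for (i in seq_len(nrow(bb)))
    block[lon >= bb$lon_min[i] & lon < bb$lon_max[i]] <- i

  # plant disks: spherical caps by great-circle distance
  pb <- spec$plant_blobs
  if (nrow(pb) > 0) {
    sin_lat <- sin(lat); cos_lat <- cos(lat)
    for (i in seq_len(nrow(pb))) {
      cosd <- sin(pb$lat[i]) * sin_lat +
        cos(pb$lat[i]) * cos_lat * cos(lon - pb$lon[i])
      lab[cosd >= cos(pb$radius[i])] <- match("plant", SCENE_CATEGORIES)
    }
  }
  storage.mode(lab) <- "integer"

  # paint RGB from prototypes
  proto_key <- matrix("building_gray", H, W)
  proto_key[lab == match("sky", SCENE_CATEGORIES)] <- "sky"
  proto_key[lab == match("road", SCENE_CATEGORIES)] <- "road"
  proto_key[lab == match("plant", SCENE_CATEGORIES)] <- "plant"
  is_building <- lab == match("building", SCENE_CATEGORIES)
  proto_key[is_building] <-
    paste0("building_", bb$color[block[is_building]])

  rgb <- array(0, c(H, W, 3))
  proto_mat <- do.call(rbind, SCENE_PROTOTYPES)
  ki <- match(proto_key, rownames(proto_mat))
  for (b in 1:3) {
    ch <- proto_mat[ki, b]
    if (spec$noise_sd > 0)
      ch <- ch + stats::runif(length(ch), -spec$noise_sd, spec$noise_sd)
    rgb[, , b] <- matrix(pmin(pmax(ch, 0), 255), H, W)
  }

  labels <- spherical_raster(lab, "equirectangular",
                             categories = SCENE_CATEGORIES)
  truth <- solid_angle_proportions(labels)
  list(rgb = spherical_raster(rgb, "equirectangular"),
       labels = labels, truth = truth, spec = spec)
}

#' Sample a set of study-like scene specifications
#'
#' Draws per-scene band fractions and planting so that the audited
#' indicator distributions emulate an urban street-scene study: road share
#' around 40% (SD ~4), sky around 19% (SD ~7), plants around 17% (SD ~10)
#' of the visual field, with street scales in roughly a 17:13:9
#' small:medium:large ratio across 39 scenes.
#'
#' @param n number of scenes
#' @param width raster width passed to each [scene_spec()]
#' @param seed RNG seed
#' @return list of `scene_spec` objects
#' @export
synthetic_scene_specs <- function(n = 39, width = 1024, seed = 1) {
  set.seed(seed)
  specs <- vector("list", n)
  scales <- sample(c("small", "medium", "large"), n, replace = TRUE,
                   prob = c(17, 13, 9) / 39)
  for (i in seq_len(n)) {
    road_f <- min(max(stats::rnorm(1, 0.40, 0.036), 0.30), 0.50)
    sky_f <- min(max(stats::rnorm(1, 0.1875, 0.0716), 0.05), 0.40)
    plant_f <- min(max(stats::rnorm(1, 0.1662, 0.1005), 0.01), 0.40)
    road_lat <- asin(2 * road_f - 1)
    sky_lat <- asin(1 - 2 * sky_f)
    # disk count set so the expected union area (allowing self-overlap
    # of independently placed caps) matches the plant target
    radius <- stats::runif(1, 0.10, 0.22)
    cap_area <- (1 - cos(radius)) / 2       # fraction of the sphere
    k <- max(1L, round(log(1 - plant_f) / log(1 - cap_area)))
    pb <- data.frame(
      lon = stats::runif(k, -pi, pi),
      lat = stats::runif(k, road_lat - 0.1, sky_lat + 0.1),
      radius = radius * stats::runif(k, 0.8, 1.2)
    )
    nb <- sample(3:8, 1)
    cuts <- sort(stats::runif(nb - 1, -pi, pi))
    bb <- data.frame(
      lon_min = c(-pi, cuts), lon_max = c(cuts, pi),
      color = sample(c("gray", "white", "red"), nb, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25)),
      stringsAsFactors = FALSE
    )
    specs[[i]] <- scene_spec(width = width, sky_lat = sky_lat,
                             road_lat = road_lat, plant_blobs = pb,
                             building_blocks = bb,
                             street_scale = scales[i], scene_id =
                               sprintf("scene_%02d", i))
  }
  specs
}

#' Effect configuration for the synthetic cohort generator
#'
#' Declares, per indicator, how responses depend on the element-layer
#' visual-pattern covariates (`pland_plant`, `pland_sky`, `pland_road`,
#' `division`, `shdi`, centered at their scene means before the linear
#' predictor is formed) and on gender.  Generative laws, chosen to respect
#' each indicator's range: EEG metrics are a logistic squashing of a
#' Gaussian linear predictor (strictly in (0,1)); SCR.n is Poisson with a
#' log link (mean ~8); SCR.Amp is the gamma sum of SCR.n exponential
#' amplitudes; HR.Avg is Gaussian with identity link; EVA ratings are
#' multinomial with baseline-category logits for levels 2 and 3.
#' Zero-effect intercepts reproduce study-like marginal levels
#' (EEG means 0.5-0.7, SCR.n ~8.1, SCR.Amp ~1.9, HR ~76.6, EVA means
#' 1.6-2.0).  Missingness emulates device dropout: whole EEG and SCR
#' blocks are lost at the stated rates, HR and ratings almost never.
#'
#' @param participants,scenes_per_participant,n_groups cohort geometry:
#'   participants are assigned cyclically to scene groups of
#'   `scenes_per_participant` scenes drawn from the audited scene pool
#' @param effects named list; each element a list with `intercept`,
#'   `beta` (named vector, or 2-row matrix for EVA levels 2 and 3),
#'   `gender`, and (linear laws) `sd`
#' @param missing named vector of block missingness rates
#' @param gender_p probability a participant is male (gender = 1)
#' @return object of class `effect_config`
#' @export
effect_config <- function(participants = 26, scenes_per_participant = 12,
                          n_groups = 4, effects = list(),
                          missing = c(EEG = 1 / 3, SCR = 0.32,
                                      HR = 0.006, EVA = 0.006),
                          gender_p = 0.5) {
  defaults <- default_effects()
  for (nm in names(effects))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], effects[[nm]])
  stopifnot(all(missing >= 0 & missing < 1))
  structure(list(participants = participants,
                 scenes_per_participant = scenes_per_participant,
                 n_groups = n_groups, effects = defaults,
                 missing = missing, gender_p = gender_p),
            class = "effect_config")
}

COVARIATE_NAMES <- c("pland_plant", "pland_sky", "pland_road",
                     "division", "shdi")

zero_beta <- function() stats::setNames(rep(0, 5), COVARIATE_NAMES)

default_effects <- function() {
  eeg_means <- c(EEG.En = 0.69, EEG.Ex = 0.51, EEG.St = 0.67,
                 EEG.Re = 0.61, EEG.In = 0.67, EEG.Fo = 0.57)
  eff <- list()
  for (nm in names(eeg_means))
    eff[[nm]] <- list(intercept = stats::qlogis(eeg_means[[nm]]),
                      beta = zero_beta(), gender = 0, sd = 0.5)
  eff$SCR.n <- list(intercept = log(8.12), beta = zero_beta(), gender = 0)
  eff$SCR.Amp <- list(scale = 0.23)  # mean amplitude per SCR, mu-S
  eff$HR.Avg <- list(intercept = 76.58, beta = zero_beta(), gender = 0,
                     sd = 10.88)
  # EVA intercepts set marginal level frequencies:
  # interest (.55,.30,.15), comfort (.30,.40,.30), vitality (.40,.40,.20)
  eva_beta <- function() rbind(`2` = zero_beta(), `3` = zero_beta())
  eff$EVA.In <- list(intercept = c(log(0.30 / 0.55), log(0.15 / 0.55)),
                     beta = eva_beta(), gender = c(0, 0))
  eff$EVA.Co <- list(intercept = c(log(0.40 / 0.30), log(0.30 / 0.30)),
                     beta = eva_beta(), gender = c(0, 0))
  eff$EVA.Vi <- list(intercept = c(log(0.40 / 0.40), log(0.20 / 0.40)),
                     beta = eva_beta(), gender = c(0, 0))
  eff
}

#' Simulate a participant-by-scene response cohort
#'
#' Draws one record per participant x assigned scene under the generative
#' laws of [effect_config()], using the element-layer covariates of the
#' supplied scene audits as exposures.  Deterministic under `seed`.
#'
#' @param audits data.frame of [audit_scene()] rows (both layers or just
#'   `constituent_elements`)
#' @param cfg an `effect_config`
#' @param seed RNG seed
#' @return response data.frame: `participant_id`, `scene_id`, `gender`,
#'   `street_scale`, the nine physiological indicators, the three ordinal
#'   ratings
#' @export
generate_cohort <- function(audits, cfg = effect_config(), seed = 1) {
  stopifnot(inherits(cfg, "effect_config"))
  a <- audits[audits$layer == "constituent_elements", , drop = FALSE]
  if (nrow(a) == 0L) stop("audits contain no constituent_elements rows")
  set.seed(seed)

  # centered covariate matrix, one row per scene
  Xs <- as.matrix(a[, COVARIATE_NAMES, drop = FALSE])
  Xs <- sweep(Xs, 2, colMeans(Xs))
  rownames(Xs) <- a$scene_id

  # scene groups and participant assignment
  n_scenes <- nrow(a)
  k <- min(cfg$scenes_per_participant, n_scenes)
  groups <- lapply(seq_len(cfg$n_groups), function(g)
    sample(a$scene_id, k))
  pid <- seq_len(cfg$participants)
  grp <- ((pid - 1L) %% cfg$n_groups) + 1L
  gender_p <- stats::rbinom(cfg$participants, 1, cfg$gender_p)

  rec <- do.call(rbind, lapply(pid, function(i)
    data.frame(participant_id = sprintf("P%02d", i),
               scene_id = groups[[grp[i]]],
               gender = gender_p[i], stringsAsFactors = FALSE)))
  rec$street_scale <- a$street_scale[match(rec$scene_id, a$scene_id)]
  X <- Xs[rec$scene_id, , drop = FALSE]
  n <- nrow(rec)
  eff <- cfg$effects

  lin_pred <- function(e) {
    drop(X %*% e$beta[COVARIATE_NAMES]) + e$gender * rec$gender +
      e$intercept
  }
  for (nm in EEG_INDICATORS) {
    e <- eff[[nm]]
    rec[[nm]] <- stats::plogis(lin_pred(e) + stats::rnorm(n, 0, e$sd))
  }
  rec$SCR.n <- stats::rpois(n, exp(lin_pred(eff$SCR.n)))
  rec$SCR.Amp <- stats::rgamma(n, shape = pmax(rec$SCR.n, 1e-9),
                               scale = eff$SCR.Amp$scale)
  rec$SCR.Amp[rec$SCR.n == 0] <- 0
  e <- eff$HR.Avg
  rec$HR.Avg <- lin_pred(e) + stats::rnorm(n, 0, e$sd)
  for (nm in EVA_INDICATORS) {
    e <- eff[[nm]]
    eta2 <- drop(X %*% e$beta[1, COVARIATE_NAMES]) +
      e$gender[1] * rec$gender + e$intercept[1]
    eta3 <- drop(X %*% e$beta[2, COVARIATE_NAMES]) +
      e$gender[2] * rec$gender + e$intercept[2]
    den <- 1 + exp(eta2) + exp(eta3)
    p <- cbind(1 / den, exp(eta2) / den, exp(eta3) / den)
    u <- stats::runif(n)
    rec[[nm]] <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
  }

  # block missingness (device dropout)
  drop_block <- function(cols, rate) {
    miss <- stats::runif(n) < rate
    for (cc in cols) rec[[cc]][miss] <<- NA
  }
  drop_block(EEG_INDICATORS, cfg$missing[["EEG"]])
  drop_block(c("SCR.n", "SCR.Amp"), cfg$missing[["SCR"]])
  drop_block("HR.Avg", cfg$missing[["HR"]])
  drop_block(EVA_INDICATORS, cfg$missing[["EVA"]])
  rec[order(rec$participant_id, rec$scene_id), , drop = FALSE]
}

#' Null cohort: responses independent of the visual pattern
#'
#' [generate_cohort()] with every covariate and gender coefficient forced
#' to zero (intercepts kept), the calibration harness for the statistics
#' module.
#'
#' @inheritParams generate_cohort
#' @export
null_cohort <- function(audits, cfg = effect_config(), seed = 1) {
  eff <- cfg$effects
  for (nm in names(eff)) {
    if (!is.null(eff[[nm]]$beta)) eff[[nm]]$beta[] <- 0
    if (!is.null(eff[[nm]]$gender)) eff[[nm]]$gender[] <- 0
  }
  cfg$effects <- eff
  generate_cohort(audits, cfg, seed = seed)
}
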