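#' Validate pipeline inputs
#'
#' Report-only checks of the raw inputs: panorama aspect ratio (must be
#' 2:1), label-raster coverage by the class scheme, response-table schema
#' and value ranges (EEG in [0,1], SCR nonnegative, heart rate positive,
#' ratings in 1..3, gender 0/1, street scale labels).  Returns all
#' violations found; an empty data.frame means a clean input set.
#'
#' @param rgb optional RGB `spherical_raster`
#' @param labels optional label `spherical_raster` of raw ids
#' @param scheme optional `class_scheme` for the label raster
#' @param responses optional response data.frame
#' @return data.frame with columns `check`, `item`, `message`
#' @export
validate_inputs <- function(rgb = NULL, labels = NULL, scheme = NULL,
                            responses = NULL) {
  v <- list()
  bad <- function(check, item, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, item = item,
                                       message = message,
                                       stringsAsFactors = FALSE)
  dims_ok <- function(x, what) {
    d <- dim(x$values)
    if (d[2] != 2L * d[1])
      bad("aspect", what,
          sprintf("expected 2:1 aspect, got %d x %d", d[2], d[1]))
  }
  if (!is.null(rgb)) {
    dims_ok(rgb, "rgb")
    if (min(rgb$values) < 0 || max(rgb$values) > 255)
      bad("range", "rgb", "channel values outside [0, 255]")
  }
  if (!is.null(labels)) {
    dims_ok(labels, "labels")
    if (!is.null(scheme)) {
      ids <- unlist(scheme$mapping, use.names = FALSE)
      present <- unique(labels$values[labels$mask])
      unmapped <- setdiff(present[!is.na(present)], ids)
      if (length(unmapped) > 0L && is.null(scheme$other))
        bad("coverage", "labels",
            paste("raw ids not covered by scheme:",
                  paste(sort(unmapped), collapse = ", ")))
    }
    if (!is.null(rgb) && !identical(dim(rgb), dim(labels)))
      bad("alignment", "labels", "label raster not aligned to panorama")
  }
  if (!is.null(responses)) {
    need <- c("participant_id", "scene_id", "gender", "street_scale",
              ALL_INDICATORS)
    miss <- setdiff(need, names(responses))
    if (length(miss) > 0L)
      bad("schema", "responses",
          paste("missing columns:", paste(miss, collapse = ", ")))
    chk_range <- function(cols, lo, hi, what) {
      for (cc in intersect(cols, names(responses))) {
        x <- responses[[cc]]
        n_bad <- sum(x < lo | x > hi, na.rm = TRUE)
        if (n_bad > 0)
          bad("range", cc, sprintf("%d values outside %s", n_bad, what))
      }
    }
    chk_range(EEG_INDICATORS, 0, 1, "[0, 1]")
    chk_range(c("SCR.n", "SCR.Amp"), 0, Inf, "[0, Inf)")
    chk_range("HR.Avg", 1e-9, Inf, "(0, Inf)")
    chk_range(EVA_INDICATORS, 1, 3, "{1, 2, 3}")
    chk_range("gender", 0, 1, "{0, 1}")
    if ("street_scale" %in% names(responses)) {
      ok <- responses$street_scale %in% c("small", "medium", "large")
      if (!all(ok))
        bad("range", "street_scale",
            sprintf("%d labels not in {small, medium, large}", sum(!ok)))
    }
  }
  if (length(v) == 0L)
    data.frame(check = character(), item = character(),
               message = character(), stringsAsFactors = FALSE)
  else do.call(rbind, v)
}

#' Run the full auditing and modelling pipeline
#'
#' Orchestrates scene auditing, response assembly, exposure-response
#' modelling and correlation reporting as one reproducible run.  Scenes
#' and responses default to the synthetic generators; pass pre-built
#' scenes (as returned by [generate_scene()], each with a `street_scale`
#' in its spec) and/or a response data.frame to analyze real inputs.
#' All randomness flows from the single `seed`, split per stage, so two
#' runs with identical arguments produce byte-identical CSV outputs.
#'
#' Outputs written under `out_dir`: `audits.csv`; per layer
#' `linear_<layer>.csv` / `multinomial_<layer>.csv` (wide coefficient
#' tables with significance stars, model p and N footers) plus `.txt`
#' renderings; `correlations.csv` and `correlation_pvalues.csv`;
#' `manifest.yaml` with the configuration snapshot and per-family record
#' counts.
#'
#' @param out_dir output directory (created if needed)
#' @param seed root RNG seed
#' @param n_scenes,width synthetic scene count and raster width (ignored
#'   when `scenes` is supplied)
#' @param scenes optional list of generated scenes
#' @param responses optional response data.frame
#' @param cfg `effect_config` for the synthetic cohort
#' @param rules `color_rules` for the color layer
#' @param connectivity patch connectivity (8 or 4)
#' @param audit_width Hammer grid width used for auditing
#' @param verbose log stage progress to stderr
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(out_dir, seed = 1, n_scenes = 39, width = 1024,
                         scenes = NULL, responses = NULL,
                         cfg = effect_config(),
                         rules = default_color_rules(),
                         connectivity = 8, audit_width = NULL,
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[panoscape] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage 1/4: scenes")
  if (is.null(scenes)) {
    specs <- synthetic_scene_specs(n_scenes, width, seed = seed + 101L)
    scenes <- stage("scenes", lapply(seq_along(specs), function(i)
      generate_scene(specs[[i]], seed = seed + 1000L + i)))
  }
  if (is.null(audit_width)) audit_width <- scenes[[1]]$labels$width

  say("stage 2/4: auditing ", length(scenes), " scenes")
  audits <- stage("audit", do.call(rbind, lapply(scenes, function(sc)
    audit_scene(sc$labels, sc$rgb, street_scale = sc$spec$street_scale,
                scene_id = sc$spec$scene_id, rules = rules,
                out_width = audit_width, connectivity = connectivity))))
  write_csv_stable(audits, file.path(out_dir, "audits.csv"))

  say("stage 3/4: responses")
  if (is.null(responses))
    responses <- stage("cohort",
                       generate_cohort(audits, cfg, seed = seed + 202L))
  write_csv_stable(responses, file.path(out_dir, "responses.csv"))

  say("stage 4/4: models")
  counts <- list()
  for (layer in c("constituent_elements", "colors")) {
    md <- assemble_model_data(audits, responses, layer)
    covs <- grep("^pland_", names(md), value = TRUE)
    covs <- c(covs, intersect(c("division", "shdi"), names(md)))
    ctrl <- c("scale_large", "scale_small", "gender")
    # with few scenes the scene-level design can be aliased; drop the
    # aliased tail (small scene sets cannot identify all terms)
    X <- cbind(1, as.matrix(md[, c(covs, ctrl)]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      say("layer ", layer, ": dropping aliased terms: ",
          paste(dropped, collapse = ", "))
      covs <- setdiff(covs, dropped)
      ctrl <- setdiff(ctrl, dropped)
    }
    lin <- stage("linear models", lapply(PHYSIO_INDICATORS, function(y)
      fit_linear(md, y, covariates = covs, controls = ctrl)))
    mult <- stage("multinomial models",
                  lapply(EVA_INDICATORS, function(y)
                    fit_multinomial(md, y, covariates = covs,
                                    controls = ctrl)))
    write_csv_stable(model_summary_table(lin),
                     file.path(out_dir, paste0("linear_", layer, ".csv")))
    write_csv_stable(model_summary_table(mult),
                     file.path(out_dir,
                               paste0("multinomial_", layer, ".csv")))
    writeLines(c(render_fits(lin), "", render_fits(mult)),
               file.path(out_dir, paste0("models_", layer, ".txt")))
    if (layer == "constituent_elements")
      counts <- list(
        EEG = lin[[1]]$n, SCR = lin[[7]]$n, HR = lin[[9]]$n,
        EVA = mult[[1]]$n)
  }

  ct <- stage("correlations", correlate(responses))
  write_csv_stable(as.data.frame(round(ct$r, 4)),
                   file.path(out_dir, "correlations.csv"),
                   row_names = TRUE)
  write_csv_stable(as.data.frame(round(ct$p, 6)),
                   file.path(out_dir, "correlation_pvalues.csv"),
                   row_names = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("panoscape")),
    seed = seed,
    scenes = length(scenes),
    audit_width = audit_width,
    connectivity = connectivity,
    records = nrow(responses),
    valid_n = counts,
    outputs = sort(list.files(out_dir))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("done: ", out_dir)
  invisible(manifest)
}

# deterministic CSV writer (no timestamps, fixed na encoding)
write_csv_stable <- function(x, path, row_names = FALSE) {
  utils::write.csv(x, path, row.names = row_names, na = "")
  invisible(path)
}

render_fits <- function(fits) {
  unlist(lapply(fits, function(f) {
    c(utils::capture.output(print(f)), "")
  }))
}
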