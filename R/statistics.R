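#' The twelve perception indicators of the response table
#'
#' Six EEG performance metrics in `[0,1]`, two skin-conductance summaries,
#' mean heart rate, and three ordinal (1-3) subjective evaluations.
#' @name indicators
#' @export
EEG_INDICATORS <- c("EEG.En", "EEG.Ex", "EEG.St", "EEG.Re", "EEG.In",
                    "EEG.Fo")

#' @rdname indicators
#' @export
PHYSIO_INDICATORS <- c(EEG_INDICATORS, "SCR.n", "SCR.Amp", "HR.Avg")

#' @rdname indicators
#' @export
EVA_INDICATORS <- c("EVA.In", "EVA.Co", "EVA.Vi")

#' @rdname indicators
#' @export
ALL_INDICATORS <- c(PHYSIO_INDICATORS, EVA_INDICATORS)

#' z-score a vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param x numeric vector with nonzero variance
#' @return standardized vector
#' @export
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Significance stars
#'
#' Three-level convention: `*` p < 0.1, `**` p < 0.05, `***` p < 0.01.
#'
#' @param p numeric vector of p-values
#' @param thresholds descending significance cut points
#' @return character vector of star strings
#' @export
significance_stars <- function(p, thresholds = c(0.1, 0.05, 0.01)) {
  stopifnot(all(diff(thresholds) < 0))
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    strrep("*", sum(pp < thresholds))
  }, "")
}

# visual-pattern covariates present in an assembled model table:
# the layer's pland_* columns plus the scene-level division and shdi
detect_covariates <- function(data) {
  c(grep("^pland_", names(data), value = TRUE),
    intersect(c("division", "shdi"), names(data)))
}

# covariate sets of the two model groups
layer_covariates <- function(layer = c("constituent_elements", "colors")) {
  layer <- match.arg(layer)
  if (layer == "constituent_elements")
    c("pland_plant", "pland_sky", "pland_road", "division", "shdi")
  else
    c("pland_green", "pland_blue", "pland_red", "division", "shdi")
}

#' Join scene audits to participant responses for one model layer
#'
#' Selects the audit rows of the requested layer, joins them to the
#' response table on `scene_id`, and adds the control dummies: street
#' scale as two indicators (`scale_large`, `scale_small`; medium is the
#' reference, being the most common scale), gender as male = 1.
#'
#' @param audits data.frame of [audit_scene()] rows
#' @param responses response data.frame (see [generate_cohort()] for the
#'   schema)
#' @param layer `"constituent_elements"` or `"colors"`
#' @return data.frame with the five layer covariates, the three control
#'   dummies, and all indicator columns
#' @export
assemble_model_data <- function(audits, responses,
                                layer = c("constituent_elements",
                                          "colors")) {
  layer <- match.arg(layer)
  a <- audits[audits$layer == layer, , drop = FALSE]
  covs <- layer_covariates(layer)
  missing_cols <- setdiff(c("scene_id", covs, "street_scale"), names(a))
  if (length(missing_cols) > 0L)
    stop("audit table lacks columns: ", paste(missing_cols, collapse = ", "))
  a_cols <- c("scene_id", covs)
  if (!("street_scale" %in% names(responses)))
    a_cols <- c(a_cols, "street_scale")
  d <- merge(responses, a[, a_cols], by = "scene_id", sort = FALSE)
  d$scale_large <- as.integer(d$street_scale == "large")
  d$scale_small <- as.integer(d$street_scale == "small")
  d[order(d$participant_id, d$scene_id), , drop = FALSE]
}

#' Standardized multiple linear regression for a physiological indicator
#'
#' Ordinary least squares of the (z-scored) outcome on the five z-scored
#' visual-pattern covariates of one layer plus the raw control dummies
#' (street scale, gender), following the exposure-response model
#' `Y = b0 + b1..b5 * visual pattern + b6 large + b7 small + b8 gender + e`.
#' Coefficients of the continuous covariates are therefore standardized
#' betas; dummy coefficients are reported as fitted.  Rows missing the
#' outcome are dropped for this model only.
#'
#' @param data output of [assemble_model_data()]
#' @param outcome column name of a continuous indicator
#' @param covariates continuous covariate names (default: the five
#'   visual-pattern indicators present in `data`)
#' @param controls dummy covariate names, entered unstandardized
#' @param standardize_xy z-score the outcome and continuous covariates
#'   before fitting (standardized betas, the reporting convention);
#'   disable to estimate on raw scales, e.g. for parameter-recovery runs
#' @return object of class `linear_fit`: coefficient table (`term`, `beta`,
#'   `se`, `p`, `stars`), `model_p` (overall F-test), `r_squared`, `n`,
#'   and the underlying `lm` fit
#' @export
fit_linear <- function(data, outcome, covariates = NULL,
                       controls = c("scale_large", "scale_small", "gender"),
                       standardize_xy = TRUE) {
  if (is.null(covariates)) covariates <- detect_covariates(data)
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + length(controls) + 1L)
    stop("not enough complete records (n = ", n, ") to fit the model")
  z <- d[, c(outcome, covariates, controls), drop = FALSE]
  if (standardize_xy)
    for (v in c(outcome, covariates)) z[[v]] <- standardize(z[[v]])
  X <- as.matrix(z[, c(covariates, controls), drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- qrX$pivot[-seq_len(qrX$rank)] - 1L
    stop("collinear design; offending columns: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(c(covariates, controls),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = z)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  tab <- data.frame(term = rownames(co), beta = co[, 1], se = co[, 2],
                    p = co[, 4], stars = significance_stars(co[, 4]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome, coefficients = tab,
                 model_p = unname(model_p), r_squared = sm$r.squared,
                 n = n, fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear model for %s (n = %d, R2 = %.3f, model p = %.4g)\n",
              x$outcome, x$n, x$r_squared, x$model_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Multinomial logistic regression for an ordinal indicator
#'
#' Maximum-likelihood fit of `log(P_n / P_1) = X b_n` for the non-reference
#' outcome levels (level 1, the lowest observed score, is the reference;
#' its logits are identically zero).  Newton iterations with analytic
#' gradient and Hessian, step-halving when a step does not improve the
#' log-likelihood, deterministic start at zero, convergence when the
#' log-likelihood changes by less than `tol`.  Per-coefficient p-values
#' are Wald tests; the overall model p is the likelihood-ratio test
#' against the intercept-only model.  Visual-pattern covariates enter
#' unstandardized by default (`standardize_x` toggles z-scoring).
#'
#' @param data output of [assemble_model_data()]
#' @param outcome column name of an ordinal indicator (values 1..3)
#' @param covariates,controls as in [fit_linear()]
#' @param standardize_x z-score the continuous covariates before fitting
#' @param tol log-likelihood convergence tolerance
#' @param max_iter Newton iteration cap
#' @return object of class `multinomial_fit`: `coefficients` (`term`,
#'   `level`, `beta`, `se`, `p`, `stars`), `model_p`, `loglik`, `n`,
#'   `levels`, fitted probabilities `prob`
#' @export
fit_multinomial <- function(data, outcome, covariates = NULL,
                            controls = c("scale_large", "scale_small",
                                         "gender"),
                            standardize_x = FALSE,
                            tol = 1e-8, max_iter = 200) {
  if (is.null(covariates)) covariates <- detect_covariates(data)
  keep <- intersect(c(covariates, controls), names(data))
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  y_raw <- d[[outcome]]
  levels_y <- sort(unique(y_raw))
  K <- length(levels_y)
  if (K < 2L) stop("outcome has a single observed level")
  y <- match(y_raw, levels_y)
  Xc <- d[, keep, drop = FALSE]
  if (standardize_x) for (v in intersect(covariates, keep))
    Xc[[v]] <- standardize(Xc[[v]])
  X <- cbind(`(Intercept)` = 1, as.matrix(Xc))
  fit <- multinom_newton(X, y, K, tol = tol, max_iter = max_iter)

  # intercept-only log-likelihood: ML probabilities are level frequencies
  n <- length(y)
  n_k <- tabulate(y, K)
  ll0 <- sum(n_k * log(n_k / n))
  df <- (K - 1) * (ncol(X) - 1)
  model_p <- if (df > 0)
    stats::pchisq(2 * (fit$loglik - ll0), df, lower.tail = FALSE)
  else NA_real_

  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(
    term = rep(colnames(X), K - 1),
    level = rep(levels_y[-1], each = ncol(X)),
    beta = as.vector(fit$beta), se = as.vector(fit$se),
    p = as.vector(p), stars = significance_stars(as.vector(p)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(outcome = outcome, coefficients = tab,
                 model_p = unname(model_p), loglik = fit$loglik, n = n,
                 levels = levels_y, prob = fit$prob,
                 converged = fit$converged, iterations = fit$iterations),
            class = "multinomial_fit")
}

# Newton-Raphson for the baseline-category multinomial logit.
# X: n x p with intercept; y: codes 1..K (1 = reference).
multinom_newton <- function(X, y, K, tol = 1e-8, max_iter = 200) {
  n <- nrow(X); p <- ncol(X); m <- K - 1
  Y <- matrix(0, n, m)
  for (k in 2:K) Y[y == k, k - 1] <- 1
  B <- matrix(0, p, m)

  probs <- function(B) {
    eta <- X %*% B
    eta <- pmin(eta, 700)           # guard exp overflow under separation
    E <- exp(eta)
    denom <- 1 + rowSums(E)
    E / denom                       # n x m, P(level k+1)
  }
  loglik <- function(B) {
    P <- probs(B)
    P1 <- 1 - rowSums(P)
    li <- ifelse(y == 1, P1, P[cbind(seq_len(n), pmax(y - 1, 1))])
    sum(log(pmax(li, 1e-300)))
  }

  ll <- loglik(B)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    P <- probs(B)
    G <- crossprod(X, Y - P)                     # p x m gradient
    H <- matrix(0, p * m, p * m)
    for (k in seq_len(m)) for (l in seq_len(m)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
        crossprod(X, X * w)
    }
    step <- tryCatch(solve(H, as.vector(G)),
                     error = function(e)
                       solve(H + diag(1e-8, nrow(H)), as.vector(G)))
    step <- matrix(step, p, m)
    lam <- 1
    repeat {
      B_new <- B + lam * step
      ll_new <- loglik(B_new)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- ll_new - ll
    B <- B_new; ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("multinomial fit did not converge in ", max_iter, " iterations")
  # separation check on the effect scale: |beta_j| * sd(x_j) diverging
  sdx <- apply(X, 2, stats::sd)
  if (max(abs(B) * sdx) > 15)
    warning("diverging coefficients: possible separation")

  P <- probs(B)
  H <- matrix(0, p * m, p * m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
    H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
      crossprod(X, X * w)
  }
  V <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-8, nrow(H))))
  SE <- matrix(sqrt(pmax(diag(V), 0)), p, m)
  prob <- cbind(1 - rowSums(P), P)
  colnames(prob) <- NULL
  list(beta = B, se = SE, loglik = ll, prob = prob,
       converged = converged, iterations = iter)
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat(sprintf(
    "Multinomial logit for %s (n = %d, ref level = %s, model p = %.4g)\n",
    x$outcome, x$n, x$levels[1], x$model_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Mixed Pearson/Spearman correlation matrix of the perception indicators
#'
#' Pearson correlation between pairs of continuous (physiological)
#' indicators; Spearman whenever an ordinal subjective-evaluation
#' indicator is involved.  Cells use pairwise-complete observations; cells
#' with fewer than `min_pairs` complete pairs are marked missing.
#'
#' @param responses response data.frame containing the indicator columns
#' @param indicators columns to correlate (default: the 12 perception
#'   indicators)
#' @param ordinal which of them are ordinal
#' @param min_pairs minimum complete pairs per cell
#' @return object of class `correlation_table` with matrices `r`, `p`,
#'   `n`, `method`, and `stars`
#' @export
correlate <- function(responses, indicators = ALL_INDICATORS,
                      ordinal = EVA_INDICATORS, min_pairs = 3) {
  indicators <- intersect(indicators, names(responses))
  m <- length(indicators)
  r <- p <- nn <- matrix(NA_real_, m, m,
                         dimnames = list(indicators, indicators))
  method <- matrix(NA_character_, m, m,
                   dimnames = list(indicators, indicators))
  for (i in seq_len(m)) {
    r[i, i] <- 1; p[i, i] <- 0
    nn[i, i] <- sum(!is.na(responses[[indicators[i]]]))
    method[i, i] <- if (indicators[i] %in% ordinal) "spearman" else "pearson"
    if (i == m) break
    for (j in (i + 1):m) {
      xi <- responses[[indicators[i]]]
      xj <- responses[[indicators[j]]]
      ok <- !is.na(xi) & !is.na(xj)
      meth <- if (indicators[i] %in% ordinal ||
                  indicators[j] %in% ordinal) "spearman" else "pearson"
      method[i, j] <- method[j, i] <- meth
      nn[i, j] <- nn[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], xj[ok], method = meth, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix(significance_stars(as.vector(p)), m, m,
                  dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, n = nn, method = method, stars = stars),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  disp <- matrix(paste0(ifelse(is.na(x$r), "", format(round(x$r, digits),
                                                      nsmall = digits)),
                        ifelse(x$stars == "", "", " "), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[upper.tri(disp)] <- ""
  print(as.data.frame(disp), right = TRUE)
  cat("significance: * p < 0.1, ** p < 0.05, *** p < 0.01;",
      "Spearman where an ordinal indicator is involved, else Pearson\n")
  invisible(x)
}

#' Fit one model family across outcomes and render a wide summary table
#'
#' Mirrors the reporting layout of the exposure-response tables: one row
#' per model term, one column pair (beta, stars) per outcome, plus model
#' significance and N rows.
#'
#' @param fits list of `linear_fit` or `multinomial_fit` objects
#' @return data.frame in wide layout
#' @export
model_summary_table <- function(fits) {
  stopifnot(length(fits) > 0)
  multi <- inherits(fits[[1]], "multinomial_fit")
  cols <- list()
  for (f in fits) {
    co <- f$coefficients
    if (multi) {
      for (lev in unique(co$level)) {
        sel <- co[co$level == lev, ]
        cols[[paste0(f$outcome, ".", lev)]] <-
          stats::setNames(paste0(format(round(sel$beta, 3), nsmall = 3),
                                 ifelse(sel$stars == "", "",
                                        paste0(" ", sel$stars))),
                          sel$term)
      }
    } else {
      cols[[f$outcome]] <-
        stats::setNames(paste0(format(round(co$beta, 3), nsmall = 3),
                               ifelse(co$stars == "", "",
                                      paste0(" ", co$stars))),
                        co$term)
    }
  }
  terms <- names(cols[[1]])
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]][terms])
  foot_p <- vapply(fits, function(f) f$model_p, 0)
  foot_n <- vapply(fits, function(f) f$n, 0)
  rep_per_fit <- length(cols) / length(fits)
  out <- rbind(out,
               c("model_p", as.vector(t(matrix(
                 rep(format(round(foot_p, 4), nsmall = 4), rep_per_fit),
                 ncol = rep_per_fit)))),
               c("n", as.vector(t(matrix(rep(as.character(foot_n),
                                             rep_per_fit),
                                         ncol = rep_per_fit)))))
  out
}
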