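test_that("standardize centers, scales, and is affine invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(30)
  expect_equal(standardize(-3 * x + 7), -standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("significance stars follow the three-level convention", {
  expect_identical(significance_stars(c(0.5, 0.09, 0.04, 0.009, NA)),
                   c("", "*", "**", "***", ""))
})

# 12-row worked fixture shared by the linear-fit oracle checks
linear_fixture <- function() {
  set.seed(77)
  d <- data.frame(x1 = rnorm(12), x2 = runif(12), g = rep(0:1, 6))
  d$y <- 1.5 + 2 * d$x1 - 0.7 * d$x2 + 0.3 * d$g + rnorm(12, 0, 0.4)
  d
}

test_that("fit_linear equals the normal-equations oracle on a fixed fixture", {
  d <- linear_fixture()
  f <- fit_linear(d, "y", covariates = c("x1", "x2"), controls = "g",
                  standardize_xy = FALSE)
  X <- cbind(1, d$x1, d$x2, d$g)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(f$coefficients$beta, as.vector(beta_hat), tolerance = 1e-10)

  # residuals orthogonal to the design
  expect_lt(max(abs(t(X) %*% stats::residuals(f$fit))), 1e-8)

  # standardized betas are invariant to affine rescaling of a covariate
  fs <- fit_linear(d, "y", covariates = c("x1", "x2"), controls = "g")
  d2 <- d; d2$x1 <- 100 * d2$x1 - 3
  fs2 <- fit_linear(d2, "y", covariates = c("x1", "x2"), controls = "g")
  expect_equal(fs$coefficients$beta, fs2$coefficients$beta,
               tolerance = 1e-10)
})

test_that("a noiseless proportional outcome gives standardized beta 1", {
  d <- data.frame(x = rnorm(40), g = rep(0:1, 20))
  d$y <- 2 * d$x
  f <- fit_linear(d, "y", covariates = "x", controls = "g")
  expect_equal(f$coefficients$beta[f$coefficients$term == "x"], 1,
               tolerance = 1e-10)
  expect_lt(f$model_p, 1e-12)
})

test_that("fit_linear names collinear columns", {
  d <- linear_fixture()
  d$x3 <- 2 * d$x1
  expect_error(fit_linear(d, "y", covariates = c("x1", "x2", "x3"),
                          controls = "g"),
               "collinear.*x3")
})

test_that("multinomial fit solves the toy contingency table in closed form", {
  d <- data.frame(x = c(rep(0, 30), rep(1, 35)),
                  y = c(rep(1, 10), rep(2, 20), rep(1, 5), rep(2, 30)))
  f <- fit_multinomial(d, "y", covariates = "x", controls = character(0))
  slope <- f$coefficients$beta[f$coefficients$term == "x"]
  expect_equal(slope, log(3), tolerance = 1e-6)
  # intercept is the log odds in the x = 0 group
  icpt <- f$coefficients$beta[f$coefficients$term == "(Intercept)"]
  expect_equal(icpt, log(20 / 10), tolerance = 1e-6)
})

test_that("intercept-only multinomial reproduces observed level frequencies", {
  set.seed(14)
  d <- data.frame(y = sample(1:3, 200, TRUE, prob = c(0.5, 0.3, 0.2)))
  f <- fit_multinomial(d, "y", covariates = character(0),
                       controls = character(0))
  freq <- as.vector(table(d$y)) / 200
  expect_equal(unname(f$prob[1, ]), freq, tolerance = 1e-7)
  expect_true(all(abs(rowSums(f$prob) - 1) < 1e-12))
})

test_that("multinomial fit agrees with nnet::multinom on a random design", {
  skip_if_not_installed("nnet")
  set.seed(31)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = runif(n), g = rbinom(n, 1, 0.5))
  eta2 <- 0.3 + 0.8 * d$x1 - 0.5 * d$x2
  eta3 <- -0.2 + 0.4 * d$x1 + 0.9 * d$g
  den <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  p1 <- 1 / den; p2 <- exp(eta2) / den
  d$y <- 1L + (u > p1) + (u > p1 + p2)
  f <- fit_multinomial(d, "y", covariates = c("x1", "x2"), controls = "g")
  ref <- nnet::multinom(factor(y) ~ x1 + x2 + g, data = d, trace = FALSE,
                        reltol = 1e-12)
  expect_equal(as.vector(t(matrix(f$coefficients$beta, ncol = 2))),
               as.vector(coef(ref)), tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("multinomial probabilities sum to one and reference logits are zero", {
  ex <- get_test_audits()
  resp <- generate_cohort(ex$audits, effect_config(), seed = 9)
  md <- assemble_model_data(ex$audits, resp, "constituent_elements")
  f <- fit_multinomial(md, "EVA.Co")
  expect_true(all(abs(rowSums(f$prob) - 1) < 1e-10))
  expect_identical(f$levels[1], 1L)  # lowest score is the reference
  expect_equal(nrow(f$coefficients), 2 * 9)
})

test_that("separation is flagged with a diverging-coefficient warning", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = c(rep(1, 20), rep(2, 20)))
  expect_warning(fit_multinomial(d, "y", covariates = "x",
                                 controls = character(0)),
                 "separation|converge")
})

test_that("correlate applies the Pearson/Spearman scheme with stars", {
  set.seed(4)
  n <- 60
  resp <- data.frame(HR.Avg = rnorm(n, 76, 10))
  resp$SCR.n <- rpois(n, 8)
  resp$SCR.Amp <- resp$SCR.n * 0.23 + rnorm(n, 0, 0.2)
  resp$EVA.Co <- sample(1:3, n, TRUE)
  ct <- correlate(resp, indicators = c("HR.Avg", "SCR.n", "SCR.Amp",
                                       "EVA.Co"))
  expect_equal(unname(diag(ct$r)), rep(1, 4))
  expect_equal(ct$r, t(ct$r))
  expect_identical(ct$method["HR.Avg", "SCR.n"], "pearson")
  expect_identical(ct$method["HR.Avg", "EVA.Co"], "spearman")
  expect_identical(ct$stars["SCR.n", "SCR.Amp"], "***")

  # perfect linear and monotone association
  d <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
                  EVA.In = c(1, 2, 2, 3))
  ct2 <- correlate(d, indicators = c("a", "b", "c", "EVA.In"))
  expect_equal(ct2$r["a", "b"], 1)
  expect_equal(ct2$r["a", "c"], -1)
  # Spearman is invariant to monotone transforms
  d2 <- data.frame(x = rnorm(30))
  d2$EVA.Vi <- exp(d2$x)
  ct3 <- correlate(d2, indicators = c("x", "EVA.Vi"))
  expect_equal(ct3$r["x", "EVA.Vi"], 1)
})

test_that("cells with too few complete pairs are marked missing", {
  d <- data.frame(HR.Avg = c(1, NA, NA, NA, 5),
                  SCR.n = c(NA, 2, 3, 4, NA))
  ct <- correlate(d, indicators = c("HR.Avg", "SCR.n"))
  expect_true(is.na(ct$r["HR.Avg", "SCR.n"]))
})

test_that("per-model sample restriction drops records per outcome family", {
  ex <- get_test_audits()
  resp <- generate_cohort(ex$audits, effect_config(), seed = 10)
  md <- assemble_model_data(ex$audits, resp, "constituent_elements")
  f_eeg <- fit_linear(md, "EEG.En")
  f_hr <- fit_linear(md, "HR.Avg")
  expect_equal(f_eeg$n, sum(!is.na(md$EEG.En)))
  expect_equal(f_hr$n, sum(!is.na(md$HR.Avg)))
  expect_gt(f_hr$n, f_eeg$n)
})
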