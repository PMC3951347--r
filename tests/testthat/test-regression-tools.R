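# Diagnostics, the drop-nonsignificant refit and per-unit effect translation.

test_that("normality diagnostics are calibrated on Gaussian residuals", {
  set.seed(401)
  rej <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    e <- rnorm(60)
    sw <- shapiro.test(e) # reference behaviour of the statistic we report
    if (sw$p.value < 0.01) rej <- rej + 1
  }
  # our wrapper on a well-specified fit should reject at the same ~1% rate
  d <- sim_gls_data(60, c(0, 1), tau2 = 1, sigma2 = 0.5, phi = 2000,
                    seed = 402, p = 1)
  fit <- fit_gls(d$y, d$X, d$coords)
  rep_out <- diagnostics(fit)
  expect_true(rep_out$normality$p > 0.001)
  se_bin <- sqrt(0.01 * 0.99 / reps)
  expect_lt(abs(rej / reps - 0.01), 3 * se_bin)
})

test_that("planted heteroscedasticity is flagged and degenerate input rejected", {
  set.seed(403)
  hits <- 0
  for (i in 1:100) {
    n <- 150
    x <- runif(n, 0, 10)
    f <- 2 * x
    e <- rnorm(n, 0, sqrt(1 + 4 * f / max(f))) # variance grows ~5x
    aux <- lm(I(e^2) ~ f)
    lme <- n * summary(aux)$r.squared
    if (pchisq(lme, 1, lower.tail = FALSE) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
  # same score test through the package interface on a planted fit
  d <- sim_gls_data(120, c(0, 3), tau2 = 1, sigma2 = 0, phi = 1,
                    seed = 404, p = 1)
  d$y <- d$y + rnorm(120, 0, 2 * abs(scale(d$X[, 1]))) # fitted-linked spread
  fit <- fit_gls(d$y, d$X, d$coords,
                 init = list(tau2 = 1, sigma2 = 0, fixed = TRUE))
  out <- diagnostics(fit)
  expect_true(is.finite(out$heteroscedasticity$statistic))
  # constant residuals are degenerate
  fake <- fit
  fake$residuals <- rep(1, 120)
  expect_error(diagnostics(fake), "constant")
  small <- fit
  small$y <- fit$y[1:5]; small$residuals <- fit$residuals[1:5]
  expect_error(diagnostics(small), "insufficient")
})

test_that("the se-overlap refit drops only weak terms and keeps strong estimates", {
  d <- sim_gls_data(120, c(0, 4, -3, 0), tau2 = 2, sigma2 = 1, phi = 2000,
                    seed = 405, p = 3)
  fit <- fit_gls(d$y, d$X, d$coords)
  red <- drop_and_refit(fit)
  expect_true("v3" %in% red$removed)   # the planted null covariate
  expect_false("v1" %in% red$removed)
  expect_lt(abs(red$beta["v1"] - fit$beta["v1"]) / abs(fit$beta["v1"]), 0.1)
  # no-op when every term is strong
  d2 <- sim_gls_data(100, c(0, 5, -5), tau2 = 1, sigma2 = 0.5, phi = 2000,
                     seed = 406, p = 2)
  fit2 <- fit_gls(d2$y, d2$X, d2$coords)
  red2 <- drop_and_refit(fit2)
  expect_identical(red2$removed, character(0))
  expect_identical(colnames(red2$design), colnames(fit2$design))
  # all-null model collapses to the intercept with a warning
  set.seed(407)
  y0 <- rnorm(60)
  X0 <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("v1", "v2")))
  co <- cbind(runif(60, 0, 1000), runif(60, 0, 1000))
  fit0 <- fit_gls(y0, X0, co, init = list(tau2 = 1, sigma2 = 0, fixed = TRUE))
  if (all(abs(fit0$beta[-1]) <= fit0$se[-1]))
    expect_warning(drop_and_refit(fit0), "intercept-only")
})

test_that("per-unit effects translate standardized coefficients exactly", {
  df <- data.frame(canopy = runif(30), conifer = runif(30),
                   elevation = runif(30, 100, 400), slope = runif(30, 0, 10),
                   dist_shore = runif(30, 0, 3000),
                   dist_lake = runif(30, 0, 2000))
  hm <- structure(df, class = c("habitat_matrix", "data.frame"),
                  standardized = FALSE)
  st <- standardize(hm)
  res <- list(beta = c("(Intercept)" = 1, elevation = 1))
  sds <- attr(st, "column_sds")
  expect_equal(effect_per_unit(res, "elevation", 0, st), 0)
  expect_equal(effect_per_unit(res, "elevation", 10, st),
               10 / sds[["elevation"]])
  expect_error(effect_per_unit(res, "bogus", 10, st), "not present")
  # independence case: equals the OLS slope on the natural scale
  set.seed(408)
  y <- 5 + 0.07 * df$elevation + rnorm(30, 0, 0.5)
  co <- cbind(runif(30, 0, 5000), runif(30, 0, 5000))
  fit <- fit_gls(y, st["elevation"], co,
                 init = list(tau2 = 1, sigma2 = 0, fixed = TRUE))
  slope_nat <- coef(lm(y ~ df$elevation))[2]
  expect_equal(effect_per_unit(fit, "elevation", 1, st),
               unname(slope_nat), tolerance = 1e-8)
})
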