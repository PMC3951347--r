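test_that("the REML log-likelihood matches a dense-algebra oracle", {
  d <- sim_gls_data(20, c(1, 2, -1), tau2 = 2, sigma2 = 5, phi = 4000,
                    seed = 101)
  Xd <- cbind(1, d$X)
  cp <- list(tau2 = 2, sigma2 = 5, phi = 4000)
  got <- reml_loglik(d$y, Xd, d$coords, cp)
  # oracle: explicit inverse and determinants, no Cholesky shortcuts
  n <- 20
  D <- as.matrix(dist(d$coords))
  S <- 2 * diag(n) + 5 * exp(-D / 4000)
  Si <- solve(S)
  bh <- solve(t(Xd) %*% Si %*% Xd, t(Xd) %*% Si %*% d$y)
  r_ <- d$y - Xd %*% bh
  want <- -0.5 * ((n - ncol(Xd)) * log(2 * pi) +
                    as.numeric(determinant(S)$modulus) +
                    as.numeric(determinant(t(Xd) %*% Si %*% Xd)$modulus) +
                    drop(t(r_) %*% Si %*% r_))
  expect_lt(abs(got - want), 1e-8)
})

test_that("independent errors reduce the GLS fit to ordinary least squares", {
  d <- sim_gls_data(60, c(3, 1.5, -2), tau2 = 4, sigma2 = 0, phi = 1,
                    seed = 102)
  fit <- fit_gls(d$y, d$X, d$coords,
                 init = list(tau2 = 1, sigma2 = 0, fixed = TRUE))
  ols <- coef(lm(d$y ~ d$X))
  expect_lt(max(abs(fit$beta - ols)), 1e-6)
  expect_identical(fit$cov_params$sigma2, 0)
  # the freely estimated fit lands at (or near) the pure-nugget boundary too
  fit2 <- fit_gls(d$y, d$X, d$coords)
  expect_lt(max(abs(fit2$beta - ols)), 0.1)
  # residuals + fitted recover the observed response
  expect_equal(fit$residuals + fit$fitted, d$y, tolerance = 1e-12)
})

test_that("the fitted REML criterion is never worse than at the truth", {
  for (seed in 1:5) {
    d <- sim_gls_data(50, c(0, 2, -1), tau2 = 1, sigma2 = 4, phi = 3000,
                      seed = 200 + seed)
    fit <- fit_gls(d$y, d$X, d$coords)
    ll_true <- reml_loglik(d$y, cbind(1, d$X), d$coords,
                           list(tau2 = 1, sigma2 = 4, phi = 3000))
    expect_gte(fit$loglik, ll_true - 1e-6)
  }
})

test_that("the REML fit agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  d <- sim_gls_data(80, c(1, 2, -1), tau2 = 1.5, sigma2 = 4, phi = 4000,
                    seed = 103)
  fit <- fit_gls(d$y, d$X, d$coords)
  df <- data.frame(y = d$y, d$X, px = d$coords[, 1], py = d$coords[, 2])
  ref <- nlme::gls(y ~ v1 + v2, data = df,
                   correlation = nlme::corExp(form = ~ px + py, nugget = TRUE),
                   method = "REML")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("coefficient recovery bias shrinks with the sample size", {
  bias <- vapply(c(40, 90, 200), function(n) {
    b <- vapply(1:30, function(s) {
      d <- sim_gls_data(n, c(0, 2), tau2 = 1, sigma2 = 2, phi = 2000,
                        seed = 3000 + 7 * n + s, p = 1)
      fit_gls(d$y, d$X, d$coords)$beta["v1"]
    }, numeric(1))
    abs(mean(b) - 2)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.05) # no growth in bias with n
  expect_lt(bias[3], 0.1)
})

test_that("degenerate designs are rejected", {
  d <- sim_gls_data(30, c(0, 1, 1), tau2 = 1, sigma2 = 1, phi = 1000,
                    seed = 104)
  Xbad <- cbind(d$X, dup = d$X[, 1])
  expect_error(fit_gls(d$y, Xbad, d$coords), "collinear")
  expect_error(fit_gls(d$y[1:5], d$X[1:5, ], d$coords[1:5, ]), "insufficient")
})
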