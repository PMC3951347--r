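# Generalized least squares with spatially autocorrelated errors:
# percentile-on-habitat regression, residual diagnostics, the
# drop-nonsignificant refit, and per-unit effect translation.

cov_kernel <- function(d, phi, family) {
  switch(family,
         exponential = exp(-d / phi),
         gaussian = exp(-(d / phi)^2),
         spherical = ifelse(d < phi,
                            1 - 1.5 * d / phi + 0.5 * (d / phi)^3, 0),
         stop("unknown covariance family: ", family))
}

# Profile REML log-likelihood of the correlation shape
# V = lambda I + (1 - lambda) R(phi), with the overall scale s^2 profiled
# out analytically. Returns the loglik plus the profiled GLS quantities.
profile_reml <- function(lambda, phi, y, X, D, family) {
  n <- length(y); p <- ncol(X)
  V <- lambda * diag(n) + (1 - lambda) * cov_kernel(D, phi, family)
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(list(loglik = -Inf))
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < p) return(list(loglik = -Inf, singular = TRUE))
  beta <- qr.coef(qrX, ys)
  rss <- sum((ys - Xs %*% beta)^2)
  s2 <- rss / (n - p)
  logdetV <- 2 * sum(log(diag(U)))
  R <- qr.R(qrX)
  logdetXVX <- 2 * sum(log(abs(diag(R))))
  ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetV + logdetXVX + (n - p))
  XtX_inv <- chol2inv(R[seq_len(p), seq_len(p), drop = FALSE])
  list(loglik = ll, beta = beta, s2 = s2, se = sqrt(s2 * diag(XtX_inv)),
       lambda = lambda, phi = phi)
}

#' REML log-likelihood at fixed spatial covariance parameters
#'
#' Evaluates the restricted log-likelihood of the linear model with error
#' covariance `Sigma = tau2 I + sigma2 k(d / phi)` at the given parameters,
#' with beta profiled by generalized least squares.
#'
#' @param y Response vector.
#' @param X Design matrix (including intercept column).
#' @param coords n x 2 site coordinates (meters).
#' @param cov_params List with `tau2`, `sigma2`, `phi`.
#' @param family Covariance family: "exponential" (default), "gaussian",
#'   "spherical".
#' @return The REML log-likelihood.
#' @export
reml_loglik <- function(y, X, coords, cov_params, family = "exponential") {
  n <- length(y); p <- ncol(X)
  D <- as.matrix(dist(coords))
  S <- cov_params$tau2 * diag(n) +
    cov_params$sigma2 * cov_kernel(D, cov_params$phi, family)
  U <- chol(S)
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xs)
  beta <- qr.coef(qrX, ys)
  rss <- sum((ys - Xs %*% beta)^2)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(U))) +
            2 * sum(log(abs(diag(qr.R(qrX))))) + rss)
}

#' Fit the percentile-on-habitat model by spatial GLS (REML)
#'
#' Maximizes the restricted likelihood of the Gaussian linear model with
#' error covariance `Sigma = tau2 I + sigma2 k(d / phi)` (nugget, partial
#' sill, range) over the nugget proportion and range, with the overall scale
#' and the regression coefficients profiled analytically. Optimization is
#' multi-start (log-spaced range starts over the inter-site distance scale)
#' and the pure-nugget boundary (sigma2 = 0, i.e. ordinary least squares) is
#' evaluated exactly as a candidate, so independent-error data reduces to
#' the OLS solution.
#'
#' @param y Response (KDE percentile at each site, 0-100).
#' @param X Standardized `habitat_matrix`, data frame or matrix of
#'   covariates (no intercept column; one is added).
#' @param coords n x 2 matrix of site coordinates in meters.
#' @param family Covariance family (default "exponential").
#' @param init Optional list with `tau2`, `sigma2`, `phi` used as an extra
#'   start; if it also has `fixed = TRUE` no optimization is done and the
#'   model is fitted by GLS at exactly these covariance parameters.
#' @param n_starts Number of log-spaced range starts (default 3).
#' @param class_label Label stored in the result.
#' @return A `regression_result`.
#' @export
fit_gls <- function(y, X, coords, family = "exponential", init = NULL,
                    n_starts = 3, class_label = "generic") {
  Xmat <- as.matrix(as.data.frame(X))
  storage.mode(Xmat) <- "double"
  y <- unname(as.numeric(y))
  n <- length(y)
  stopifnot(nrow(Xmat) == n, nrow(coords) == n)
  if (n <= ncol(Xmat) + 3)
    stop("insufficient sites: need n > number of covariates + 3")
  design <- cbind("(Intercept)" = 1, Xmat)
  if (qr(design)$rank < ncol(design))
    stop("collinear design: near-singular covariate matrix")
  D <- as.matrix(dist(coords))
  dmax <- max(D)

  if (!is.null(init) && isTRUE(init$fixed)) {
    tot <- init$tau2 + init$sigma2
    lam <- if (tot > 0) init$tau2 / tot else 1
    phi <- if (is.null(init$phi) || init$sigma2 == 0) dmax / 4 else init$phi
    # correlation shape fixed at the caller's parameters; the overall scale
    # is still profiled by REML
    best <- profile_reml(lam, phi, y, design, D, family)
  } else {
    starts <- expand.grid(
      phi = exp(seq(log(0.05 * dmax), log(0.5 * dmax), length.out = n_starts)),
      lambda = c(0.2, 0.6))
    if (!is.null(init)) {
      tot <- init$tau2 + init$sigma2
      starts <- rbind(starts, data.frame(phi = init$phi,
                                         lambda = init$tau2 / max(tot, 1e-12)))
    }
    cands <- list()
    for (i in seq_len(nrow(starts))) {
      par0 <- c(qlogis(min(max(starts$lambda[i], 1e-4), 1 - 1e-4)),
                log(starts$phi[i]))
      opt <- tryCatch(
        optim(par0, function(par) {
          lam <- min(max(plogis(par[1]), 1e-6), 1 - 1e-9)
          phi <- exp(par[2])
          if (!is.finite(phi) || phi <= 0) return(1e10)
          ll <- profile_reml(lam, phi, y, design, D, family)$loglik
          if (!is.finite(ll)) 1e10 else -ll
        }, method = "Nelder-Mead",
        control = list(reltol = 1e-10, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9)
        cands[[length(cands) + 1]] <-
          profile_reml(plogis(opt$par[1]), exp(opt$par[2]), y, design, D, family)
    }
    # exact pure-nugget boundary candidate (OLS)
    cands[[length(cands) + 1]] <- profile_reml(1, dmax / 4, y, design, D, family)
    lls <- vapply(cands, `[[`, numeric(1), "loglik")
    if (all(!is.finite(lls)))
      stop("fit failure: non-finite likelihood at all starts")
    best <- cands[[which.max(lls)]]
  }

  beta <- drop(best$beta)
  names(beta) <- colnames(design)
  se <- best$se
  names(se) <- colnames(design)
  fitted <- unname(drop(design %*% beta))
  tau2 <- best$s2 * best$lambda
  sigma2 <- best$s2 * (1 - best$lambda)
  structure(list(beta = beta, se = se,
                 cov_params = list(tau2 = tau2, sigma2 = sigma2,
                                   phi = best$phi),
                 loglik = best$loglik, residuals = y - fitted,
                 fitted = fitted, y = y, design = design, coords = coords,
                 family = family, class_label = class_label,
                 removed = character(0)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("spatial GLS (%s, REML) for class '%s': n = %d\n",
              x$family, x$class_label, length(x$y)))
  tab <- data.frame(beta = round(x$beta, 4), se = round(x$se, 4))
  print(tab)
  cat(sprintf("cov: tau2 = %.3f, sigma2 = %.3f, phi = %.0f m; logLik = %.3f\n",
              x$cov_params$tau2, x$cov_params$sigma2, x$cov_params$phi,
              x$loglik))
  if (length(x$removed))
    cat("removed covariates:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Residual diagnostics for a spatial GLS fit
#'
#' Residuals are decorrelated with the fitted covariance (whitened by the
#' inverse Cholesky factor); normality is then assessed with the
#' Shapiro-Wilk statistic and homoscedasticity with a score test regressing
#' squared whitened residuals on whitened fitted values (LM = n R^2 against
#' chi-square with 1 df).
#'
#' @param result A `regression_result`.
#' @return List with `normality` (statistic, p) and `heteroscedasticity`
#'   (statistic, p).
#' @export
diagnostics <- function(result) {
  n <- length(result$y)
  if (n < 8) stop("insufficient data for diagnostics (n < 8)")
  if (sd(result$residuals) == 0) stop("degenerate input: constant residuals")
  D <- as.matrix(dist(result$coords))
  cp <- result$cov_params
  S <- cp$tau2 * diag(n) + cp$sigma2 * cov_kernel(D, cp$phi, result$family)
  # tiny ridge guards the factorization when the fitted nugget is ~0 and
  # sites nearly coincide
  U <- chol(S + 1e-8 * (cp$tau2 + cp$sigma2) * diag(n))
  e <- drop(backsolve(U, result$residuals, transpose = TRUE))
  f <- drop(backsolve(U, result$fitted, transpose = TRUE))
  sw <- shapiro.test(e)
  aux <- lm(I(e^2) ~ f)
  r2 <- summary(aux)$r.squared
  lme <- n * r2
  list(normality = list(statistic = unname(sw$statistic), p = sw$p.value),
       heteroscedasticity = list(statistic = lme,
                                 p = pchisq(lme, df = 1, lower.tail = FALSE)))
}

#' Drop non-significant covariates and refit
#'
#' Removes every non-intercept covariate whose interval `beta +/- se`
#' contains zero ("standard error overlaps zero"; `rule = "z"` instead uses
#' `beta +/- 1.96 se`), then refits the reduced design. The intercept is
#' always retained. The reduced result records the removed covariates.
#'
#' @param result A fitted `regression_result`.
#' @param rule "se" (default) or "z".
#' @return A `regression_result` for the reduced model (identical covariate
#'   set when nothing is removed).
#' @export
drop_and_refit <- function(result, rule = c("se", "z")) {
  rule <- match.arg(rule)
  mult <- if (rule == "se") 1 else 1.96
  terms <- setdiff(colnames(result$design), "(Intercept)")
  drop_ <- terms[abs(result$beta[terms]) <= mult * result$se[terms]]
  if (!length(drop_)) return(result)
  keep <- setdiff(terms, drop_)
  if (!length(keep)) {
    warning("all covariates removed; returning intercept-only fit")
    Xr <- matrix(numeric(0), nrow = length(result$y), ncol = 0)
  } else {
    Xr <- result$design[, keep, drop = FALSE]
  }
  out <- fit_gls(result$y, Xr, result$coords, family = result$family,
                 class_label = result$class_label)
  out$removed <- drop_
  out$rule <- rule
  out
}

#' Translate a standardized coefficient to a per-unit effect
#'
#' Predicted change in KDE percentile for a `delta` change of the covariate
#' in natural units: `beta_std * delta / column_sd`.
#'
#' @param result A `regression_result`.
#' @param covariate Covariate name.
#' @param delta Change in natural units (e.g. 10 for "per 10 m elevation").
#' @param matrix The standardized `habitat_matrix` the model was fitted on
#'   (source of the column sds).
#' @return Predicted percentile change.
#' @export
effect_per_unit <- function(result, covariate, delta, matrix) {
  sds <- attr(matrix, "column_sds")
  if (!covariate %in% names(result$beta) || !covariate %in% names(sds))
    stop("covariate '", covariate, "' not present in model or matrix")
  unname(result$beta[covariate] * delta / sds[covariate])
}
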