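# Simulation helper: correlated Gaussian errors on random coordinates.
sim_gls_data <- function(n, beta, tau2, sigma2, phi, seed,
                         extent = 20000, p = length(beta) - 1) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  D <- as.matrix(dist(coords))
  S <- tau2 * diag(n) + sigma2 * exp(-D / phi)
  err <- drop(t(chol(S)) %*% rnorm(n))
  y <- drop(beta[1] + X %*% beta[-1] + err)
  list(y = y, X = X, coords = coords)
}

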