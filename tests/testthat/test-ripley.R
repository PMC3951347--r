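test_that("K is zero when all pairs exceed the distance grid", {
  r <- rect_region(100000, 40000)
  p <- point_pattern(c(5, 30, 55, 80, 95) * 1000,
                     c(5, 35, 5, 35, 20) * 1000, region = r)
  ke <- estimate_k(p, t_grid = c(1000, 2000), correction = "none")
  expect_identical(ke$K_hat, c(0, 0))
  expect_equal(ke$L_hat, -c(1000, 2000))
})

test_that("uncorrected K matches the double-loop pair-count oracle exactly", {
  r <- rect_region(1000, 1000)
  # fixed toy configuration
  p <- point_pattern(c(100, 150, 180, 600, 620, 900),
                     c(100, 120, 400, 600, 650, 200), region = r)
  t_grid <- c(50, 100, 250, 500, 1000)
  ke <- estimate_k(p, t_grid, correction = "none")
  expect_identical(ke$K_hat, k_oracle(p$x, p$y, t_grid, r$area))
  # random patterns
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    pp <- point_pattern(x, y, region = r)
    ke <- estimate_k(pp, t_grid, correction = "none")
    expect_identical(ke$K_hat, k_oracle(x, y, t_grid, r$area))
    expect_true(all(diff(ke$K_hat) >= 0))
  }
})

test_that("the L transform obeys its identities and round-trips", {
  t <- c(1000, 2000, 5000)
  expect_equal(l_transform(pi * t^2, t), rep(0, 3))
  expect_equal(l_transform(4 * pi * t^2, t), t)
  expect_equal(l_transform(rep(0, 3), t), -t)
  expect_error(l_transform(c(-1, 0, 0), t), "non-negative")
  K <- c(3e5, 4e7, 9e8)
  expect_equal(l_inverse(l_transform(K, t), t), K, tolerance = 1e-12)
})

test_that("edge correction removes the boundary bias of K under CSR", {
  r <- rect_region(10000, 10000)
  t_test <- 2500 # a quarter of the window width
  set.seed(7)
  reps <- 150; n <- 30
  diff_iso <- diff_none <- numeric(reps)
  for (i in seq_len(reps)) {
    xy <- sample_csr(r, n)
    p <- point_pattern(xy[, 1], xy[, 2], region = r)
    diff_none[i] <- estimate_k(p, t_test, "none")$K_hat - pi * t_test^2
    diff_iso[i] <- estimate_k(p, t_test, "isotropic")$K_hat - pi * t_test^2
  }
  expect_lt(abs(mean(diff_iso)), abs(mean(diff_none)))
  # uncorrected K is substantially biased low at this range
  expect_lt(mean(diff_none), -0.1 * pi * t_test^2)
  # corrected mean L within 3 Monte-Carlo SEs of the CSR expectation 0
  L_iso <- sqrt((diff_iso + pi * t_test^2) / pi) - t_test
  expect_lt(abs(mean(L_iso)), 3 * sd(L_iso) / sqrt(reps))
})

test_that("the CSR envelope flags strong clustering and stays quiet on its own draws", {
  r <- rect_region(10000, 10000)
  set.seed(5)
  hits <- 0
  for (i in 1:40) {
    # Thomas process with sigma = 1% of the window width: tight clumps
    ctr <- sample_csr(r, 5)
    idx <- sample.int(5, 60, replace = TRUE)
    x <- pmin(pmax(ctr[idx, 1] + rnorm(60, 0, 100), 1), 9999)
    y <- pmin(pmax(ctr[idx, 2] + rnorm(60, 0, 100), 1), 9999)
    p <- point_pattern(x, y, region = r)
    env <- csr_envelope(p, n_sims = 19, alpha = 0.05, seed = 100 + i,
                        t_grid = c(500, 1000), correction = "none")
    if (env$classification[1] == "clustered") hits <- hits + 1
  }
  expect_gte(hits, 38) # >= 95% detection
  # an envelope of a CSR pattern classifies as CSR at typical rates
  xy <- sample_csr(r, 60, seed = 77)
  p <- point_pattern(xy[, 1], xy[, 2], region = r)
  env <- csr_envelope(p, n_sims = 99, alpha = 0.01, seed = 8,
                      t_grid = c(1000, 2000, 3000), correction = "none")
  expect_true(all(env$lower <= env$upper))
  # each band has a 2% pointwise false-positive rate; most bands stay CSR
  expect_gte(sum(env$classification == "CSR"), 2)
})

test_that("insufficient points and oversized grids are reported", {
  r <- rect_region()
  p1 <- point_pattern(5, 5, region = r)
  expect_error(estimate_k(p1, c(100, 200)), "insufficient")
  p2 <- point_pattern(c(100, 300), c(100, 400), region = r)
  expect_warning(estimate_k(p2, c(1000, 1e6), correction = "none"),
                 "diameter")
})

test_that("clustered_up_to reads the initial run of clustered bands", {
  env <- structure(list(t_grid = c(1000, 2000, 3000),
                        classification = c("clustered", "clustered", "CSR")),
                   class = "envelope")
  expect_equal(clustered_up_to(env), 2000)
  env$classification <- c("CSR", "clustered", "clustered")
  expect_equal(clustered_up_to(env), 0)
})
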