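test_that("simulated kill sites respect the region support and the seed", {
  f <- small_fields()
  tr <- sim_truth(c(1, 0, 0.5, -0.5, -0.5, 0), 120, seed = 9)
  p <- simulate_kill_sites(f, tr, "a")
  expect_identical(p$n, 120L)
  expect_true(all(region_contains(p$region, p$x, p$y)))
  p2 <- simulate_kill_sites(f, tr, "a")
  expect_identical(cbind(p$x, p$y), cbind(p2$x, p2$y))
  # clustered variant too
  trc <- sim_truth(c(0, 0, 0, 0, 0, 0), 80,
                   cluster_params = list(parent_intensity = 10 / 60e6,
                                         offspring_mean = 8, sigma = 400),
                   seed = 5)
  pc <- simulate_kill_sites(f, trc, "b")
  expect_true(all(region_contains(pc$region, pc$x, pc$y)))
  # clustering shrinks nearest-neighbour distances relative to CSR
  nnd <- function(q) {
    dm <- as.matrix(dist(cbind(q$x, q$y))); diag(dm) <- Inf
    mean(apply(dm, 1, min))
  }
  xy <- sample_csr(f$region, 80, seed = 5)
  expect_lt(nnd(pc), nnd(point_pattern(xy[, 1], xy[, 2], "csr", f$region)))
})

test_that("with zero coefficients the sampler matches an independent CSR oracle", {
  f <- small_fields()
  region <- f$region
  bb <- region_bbox(region)
  # independent rejection sampler written from scratch against the oracle
  # point-in-ring test on a coarse acceptance: plain runif over the bbox,
  # keep the first n falling in the region
  csr_oracle <- function(n) {
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      cand <- cbind(runif(4 * n, bb[1], bb[2]), runif(4 * n, bb[3], bb[4]))
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        inb <- pip_oracle(cand[i, 1], cand[i, 2], region$boundary[[1]])
        inl <- any(vapply(region$lakes, function(l)
          pip_oracle(cand[i, 1], cand[i, 2], l), logical(1)))
        inb && !inl
      }, logical(1))
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), ]
  }
  nnd <- function(xy) {
    dm <- as.matrix(dist(xy)); diag(dm) <- Inf
    mean(apply(dm, 1, min))
  }
  n <- 40; reps <- 200
  set.seed(31)
  mine <- vapply(seq_len(reps), function(r) {
    tr <- sim_truth(rep(0, 6), n, seed = 1000 + r)
    p <- simulate_kill_sites(f, tr)
    nnd(cbind(p$x, p$y))
  }, numeric(1))
  ref <- vapply(seq_len(reps), function(r) nnd(csr_oracle(n)), numeric(1))
  # paired-sampler oracle: same mean NND within 3 Monte-Carlo SEs
  se <- sqrt(var(mine) / reps + var(ref) / reps)
  expect_lt(abs(mean(mine) - mean(ref)), 3 * se)
  # loose closed-form sanity: the unbounded-CSR expectation 0.5 / sqrt(n / A)
  # sits below the bounded-window mean (points near the coast lack outward
  # neighbours), so only an order-of-magnitude band is meaningful here
  closed <- 0.5 / sqrt(n / region$area)
  expect_lt(abs(mean(mine) - closed) / closed, 0.30)
})

test_that("a strong conifer preference shifts points onto conifer-rich cells", {
  f <- small_fields()
  region_mean <- mean(f$layers$conifer[f$mask])
  hits <- 0
  for (r in 1:100) {
    tr <- sim_truth(c(0, 0, 0, 2, 0, 0), 50, seed = 2000 + r)
    p <- simulate_kill_sites(f, tr)
    idx <- killzones:::cell_index(f, p$x, p$y)
    v <- f$layers$conifer[idx$lin]
    if (mean(v, na.rm = TRUE) > region_mean) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("pathological intensities fail loudly", {
  f <- small_fields()
  expect_error(simulate_kill_sites(f, sim_truth(c(800, 0, 0, 0, 0, 0), 10)),
               "sampling failure|intensity")
  expect_error(sim_truth(c(1, 2, 3), 10))
  expect_error(sim_truth(rep(0, 6), 0))
})
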