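test_that("LSCV matches the brute-force leave-one-out oracle", {
  set.seed(13)
  x <- runif(25, 0, 1000); y <- runif(25, 0, 1000)
  r <- rect_region(1000, 1000)
  p <- point_pattern(x, y, region = r)
  for (h in c(120, 200, 350)) {
    got <- lscv_score(p, h)
    want <- lscv_oracle(x, y, h)
    expect_lt(abs(got - want) / abs(want), 1e-6)
  }
})

test_that("LSCV is scale equivariant and finite across four orders of magnitude", {
  set.seed(17)
  r1 <- rect_region(1000, 1000)
  x <- runif(30, 0, 1000); y <- runif(30, 0, 1000)
  p1 <- point_pattern(x, y, region = r1)
  c_ <- 7.3
  p2 <- point_pattern(x * c_, y * c_, region = rect_region(1000 * c_, 1000 * c_))
  for (h in c(50, 150, 400)) # LSCV(ch; cX) = LSCV(h; X) / c^2
    expect_equal(lscv_score(p2, c_ * h), lscv_score(p1, h) / c_^2,
                 tolerance = 1e-12)
  xy <- sample_csr(r1, 50, seed = 23)
  p <- point_pattern(xy[, 1], xy[, 2], region = r1)
  for (h in 10^seq(0, 4, by = 0.5))
    expect_true(is.finite(lscv_score(p, h)))
})

test_that("selected bandwidths sit near the normal-reference scale for Gaussian data", {
  set.seed(19)
  sigma <- 800
  x <- rnorm(400, 0, sigma); y <- rnorm(400, 0, sigma)
  w <- 5 * sigma
  r <- rect_region(10 * sigma, 10 * sigma)
  p <- point_pattern(x + w, y + w, region = r)
  h <- select_bandwidth(p)
  href <- sigma * 400^(-1 / 6)
  expect_gte(h, 0.3 * href)
  expect_lte(h, 3 * href)
})

test_that("duplicating every point never increases the selected bandwidth", {
  set.seed(23)
  r <- rect_region(5000, 5000)
  xy <- sample_csr(r, 25)
  p1 <- point_pattern(xy[, 1], xy[, 2], region = r)
  p2 <- point_pattern(rep(xy[, 1], 2), rep(xy[, 2], 2), region = r)
  h1 <- suppressWarnings(select_bandwidth(p1))
  h2 <- suppressWarnings(select_bandwidth(p2)) # warns about jittered repeats
  expect_lte(h2, h1)
  # the first warning announces the jittered repeats
  w <- tryCatch(select_bandwidth(p2), warning = function(w) conditionMessage(w))
  expect_match(w, "coincident")
})

test_that("a tight cluster with one outlier still yields a finite bandwidth", {
  set.seed(29)
  r <- rect_region(10000, 10000)
  x <- c(rnorm(29, 2000, 50), 9000)
  y <- c(rnorm(29, 2000, 50), 9000)
  p <- point_pattern(x, y, region = r)
  h <- suppressWarnings(select_bandwidth(p))
  expect_true(is.finite(h) && h > 0)
})

test_that("KDE surfaces conserve unit mass, place the mode and keep symmetry", {
  r <- small_island()
  # one point: mode at the containing cell
  ctr <- colMeans(sample_csr(r, 200, seed = 3))
  p1 <- point_pattern(ctr[1], ctr[2], region = r)
  s1 <- kde_surface(p1, h = 500, cell_size = 200)
  expect_equal(sum(s1$density[s1$mask]) * s1$cell_size^2, 1, tolerance = 1e-3)
  top <- which(s1$density == max(s1$density, na.rm = TRUE), arr.ind = TRUE)
  idx <- killzones:::cell_index(s1, ctr[1], ctr[2])
  expect_lte(max(abs(top[1, ] - c(idx$row, idx$col))), 1)
  # two well-separated points on a symmetric window: equal mode heights
  rs <- rect_region(8000, 4000)
  p2 <- point_pattern(c(2000, 6000), c(2000, 2000), region = rs)
  s2 <- kde_surface(p2, h = 300, cell_size = 100)
  i1 <- killzones:::cell_index(s2, 2000 - 50, 2000 - 50)
  i2 <- killzones:::cell_index(s2, 6000 - 50, 2000 - 50)
  expect_equal(s2$density[i1$lin], s2$density[i2$lin], tolerance = 1e-6)
  expect_warning(kde_surface(p2, h = 100, cell_size = 100), "coarser")
})

test_that("percentile transform is a monotone relabelling of density", {
  r <- small_island()
  xy <- sample_csr(r, 60, seed = 31)
  p <- point_pattern(xy[, 1], xy[, 2], region = r)
  s <- kde_surface(p, h = 800, cell_size = 200)
  ps <- percentile_transform(s)
  dv <- s$density[s$mask]; pv <- ps$percentile[s$mask]
  expect_equal(max(pv), 100)
  ord_d <- order(dv); ord_p <- order(pv)
  expect_true(all(pv[ord_d] == sort(pv))) # same ordering up to ties
  # max-density cell carries percentile 100
  expect_equal(pv[which.max(dv)], 100)
  # p_star: the top-p% mass region really holds p% of mass
  w <- dv * s$cell_size^2
  for (p_ in c(10, 30, 70)) {
    sel <- ps$p_star[s$mask] <= p_
    expect_equal(sum(w[sel]), p_ / 100, tolerance = 0.02)
  }
})

test_that("a uniform surface makes the top 30% cover 30% of the area", {
  dens <- matrix(1, 20, 30)
  s <- manual_surface(dens)
  ps <- percentile_transform(s)
  core <- extract_core(ps, 30)
  expect_equal(core$n_cells, round(0.3 * 600), tolerance = 1)
})

test_that("core extraction counts components and areas correctly", {
  # two disjoint square bumps on a flat background
  dens <- matrix(1, 20, 40)
  dens[3:6, 3:6] <- 50
  dens[14:17, 30:33] <- 50
  s <- manual_surface(dens)
  ps <- percentile_transform(s)
  mass_bumps <- sum(dens[dens == 50]) / sum(dens) * 100
  core <- extract_core(ps, mass_bumps)
  expect_identical(core$n_polygons, 2L)
  expect_identical(core$n_cells, 32L)
  # ring signed areas add up to the cell-count area (holes negative)
  ring_sum <- sum(vapply(core$polygons, function(pg) pg$area, numeric(1)))
  expect_equal(ring_sum, core$total_area, tolerance = 0.01 * core$total_area)
  # p -> 100 approaches the full region area
  big <- extract_core(ps, 99.9)
  expect_gte(big$n_cells, 0.98 * sum(s$mask))
  # empty core at a percentile below the densest cell's own mass
  spiky <- manual_surface(matrix(c(1e6, rep(1e-9, 99)), 10, 10))
  e <- extract_core(percentile_transform(spiky), 1)
  expect_identical(e$n_polygons, 0L)
  expect_identical(e$total_area, 0)
})

test_that("core polygonization handles holes and diagonal contacts", {
  # a ring of high cells with a hole in the middle
  dens <- matrix(1, 15, 15)
  dens[5:11, 5:11] <- 100
  dens[7:9, 7:9] <- 1 # hole
  s <- manual_surface(dens)
  ps <- percentile_transform(s)
  mass <- sum(dens[dens == 100]) / sum(dens) * 100
  core <- extract_core(ps, mass + 0.01)
  expect_identical(core$n_polygons, 1L)
  areas <- vapply(core$polygons, function(pg) pg$area, numeric(1))
  expect_true(any(areas < 0)) # the hole ring, negative orientation
  expect_equal(sum(areas), core$total_area, tolerance = 1e-9)
  # diagonal contact: two cells sharing a corner are one 8-connected polygon
  dens2 <- matrix(1, 6, 6)
  dens2[2, 2] <- 100; dens2[3, 3] <- 100
  s2 <- manual_surface(dens2)
  mass2 <- 200 / sum(dens2) * 100
  core2 <- extract_core(percentile_transform(s2), mass2 + 0.01)
  expect_identical(core2$n_polygons, 1L)
  expect_identical(core2$n_cells, 2L)
})

test_that("the Monte-Carlo core search rejects tiny iteration counts", {
  r <- small_island()
  xy <- sample_csr(r, 30, seed = 41)
  p <- point_pattern(xy[, 1], xy[, 2], region = r)
  s <- kde_surface(p, 1000, cell_size = 300)
  expect_error(core_percentile(p, s, n_iter = 50), "at least 100")
})
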