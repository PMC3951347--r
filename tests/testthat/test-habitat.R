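test_that("buffer means are exact on constant layers and match the cell oracle", {
  r <- rect_region(3000, 3000)
  nr <- 100; nc <- 100 # 30 m cells
  mk <- function(v) matrix(v, nr, nc)
  stack <- raster_stack(0, 3000, 30,
                        layers = list(elevation = mk(123.4), slope = mk(2),
                                      canopy = mk(0.5), conifer = mk(0.25),
                                      dist_shore = mk(10), dist_lake = mk(20)),
                        mask = matrix(TRUE, nr, nc), region = r)
  v <- buffer_stats(c(1507, 1502), stack, diameter = 100)
  expect_identical(unname(v["elevation"]), 123.4)
  expect_equal(attr(v, "buffer_area_ha"), 0.79, tolerance = 0.01)
  # cell selection against an independent double-loop center-distance test
  set.seed(3)
  elev <- matrix(runif(nr * nc, 100, 300), nr, nc)
  stack$layers$elevation <- elev
  for (site in list(c(1507, 1502), c(800, 2200), c(60, 60))) {
    got <- buffer_stats(site, stack, diameter = 100)["elevation"]
    sel <- c()
    for (rr in 1:nr) for (cc in 1:nc) {
      cx <- 0 + (cc - 0.5) * 30; cy <- 3000 - (rr - 0.5) * 30
      if ((cx - site[1])^2 + (cy - site[2])^2 <= 50^2)
        sel <- c(sel, elev[rr, cc])
    }
    expect_equal(unname(got), mean(sel))
  }
})

test_that("buffers clipped to the coast use inside cells only, or fail when empty", {
  f <- small_fields()
  # a site very near the coast: mean must come from masked-in cells only
  cc <- cell_centers(f)
  edge_cell <- which(f$mask & f$layers$dist_shore < 2 * f$cell_size)[1]
  site <- c(cc$x[edge_cell], cc$y[edge_cell])
  v <- buffer_stats(site, f, diameter = 300)
  expect_true(all(is.finite(v)))
  # far outside the island every cell is masked out
  bb <- region_bbox(f$region)
  expect_error(buffer_stats(c(bb[1] - 5000, bb[3] - 5000), f, diameter = 100),
               "no masked-in cells")
})

test_that("standardization gives exact z-scores and inverts cleanly", {
  df <- data.frame(canopy = c(0.2, 0.4, 0.6), conifer = c(0.1, 0.3, 0.2),
                   elevation = c(100, 200, 300), slope = c(1, 2, 3),
                   dist_shore = c(50, 150, 250), dist_lake = c(10, 20, 40))
  hm <- structure(df, class = c("habitat_matrix", "data.frame"),
                  standardized = FALSE)
  st <- standardize(hm)
  for (col in names(st)) {
    expect_lt(abs(mean(st[[col]])), 1e-10)
    expect_lt(abs(sd(st[[col]]) - 1), 1e-10)
  }
  back <- unstandardize(st)
  expect_equal(as.matrix(as.data.frame(back)), as.matrix(df),
               tolerance = 1e-9, ignore_attr = TRUE)
  # two-row case: sample-sd convention gives +/- 1/sqrt(2)
  hm2 <- structure(df[1:2, ], class = c("habitat_matrix", "data.frame"),
                   standardized = FALSE)
  st2 <- standardize(hm2)
  expect_equal(st2$elevation, c(-0.7071, 0.7071), tolerance = 1e-4)
  # degenerate constant column
  df3 <- df; df3$slope <- 2
  hm3 <- structure(df3, class = c("habitat_matrix", "data.frame"),
                   standardized = FALSE)
  expect_error(standardize(hm3), "slope")
})

test_that("habitat matrices carry extraction metadata and pool across classes", {
  f <- small_fields()
  tr <- sim_truth(rep(0, 6), 25, seed = 51)
  p <- simulate_kill_sites(f, tr, "a")
  hm <- habitat_matrix(p, f, diameter = 100)
  expect_identical(nrow(hm), 25L)
  expect_identical(attr(hm, "buffer_area_ha"), pi * 50^2 / 1e4)
  expect_false(anyNA(as.matrix(hm)))
  st <- standardize(hm)
  expect_true(attr(st, "standardized"))
  expect_identical(names(attr(st, "column_sds")), names(hm))
})
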