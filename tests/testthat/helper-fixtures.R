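# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive double loops / closed forms, independent of the package's
# computational paths.

# simple rectangular window as a study_region
rect_region <- function(w = 10000, h = 6000) {
  ring <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  study_region(ring)
}

# small island reused across tests (cached per session)
small_island <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_island(42, target_area = 60e6)
    cache
  }
})

small_fields <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_habitat_fields(small_island(), cell_size = 100,
                                        seed = 7)
    cache
  }
})

# independent ray-casting point-in-ring (R, scalar loop)
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# brute-force uncorrected Ripley K: explicit double loop over ordered pairs
k_oracle <- function(x, y, t_grid, area) {
  n <- length(x)
  K <- numeric(length(t_grid))
  for (b in seq_along(t_grid)) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= t_grid[b]) cnt <- cnt + 1
    }
    K[b] <- cnt * (area / (n * (n - 1)))
  }
  K
}

# brute-force LSCV: explicit leave-one-out loop plus numeric integration of
# the squared density on a fine grid (trapezoid on a Gaussian converges
# superexponentially, so spacing h/4 with an 8h margin is ample for 1e-6)
lscv_oracle <- function(x, y, h) {
  n <- length(x)
  spacing <- h / 4
  gx <- seq(min(x) - 8 * h, max(x) + 8 * h, by = spacing)
  gy <- seq(min(y) - 8 * h, max(y) + 8 * h, by = spacing)
  fhat <- matrix(0, length(gx), length(gy))
  for (i in seq_len(n))
    fhat <- fhat + outer(gx, gy, function(a, b)
      exp(-((a - x[i])^2 + (b - y[i])^2) / (2 * h^2)))
  fhat <- fhat / (n * 2 * pi * h^2)
  int_f2 <- sum(fhat^2) * spacing^2
  loo <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
      s <- s + exp(-d2 / (2 * h^2)) / (2 * pi * h^2)
    }
    loo <- loo + s / (n - 1)
  }
  int_f2 - (2 / n) * loo
}

# segment-segment proper intersection test for the ring-simplicity oracle
segs_intersect <- function(p1, p2, p3, p4) {
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- ccw(p3, p4, p1); d2 <- ccw(p3, p4, p2)
  d3 <- ccw(p1, p2, p3); d4 <- ccw(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# a kde_surface with prescribed density values on a rectangle grid, for
# percentile/extraction tests that need exact control of the surface
manual_surface <- function(dens, cell_size = 100, region = NULL) {
  nr <- nrow(dens); nc <- ncol(dens)
  mask <- matrix(TRUE, nr, nc)
  dens <- dens / (sum(dens) * cell_size^2)
  structure(list(xmin = 0, ymax = nr * cell_size, cell_size = cell_size,
                 nrow = nr, ncol = nc, density = dens, mask = mask,
                 bandwidth = cell_size, renorm_mass = 1, region = region),
            class = "kde_surface")
}
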