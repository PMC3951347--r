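# Raster containers and the synthetic habitat-field generator.
#
# Grids use center-of-cell registration with row 1 at the north edge:
# cell (r, c) has center (xmin + (c - 0.5) * cs, ymax - (r - 0.5) * cs).
# Masked-out cells carry NA; the ESRI ASCII writer substitutes the nodata
# sentinel.

#' Construct a raster stack
#'
#' @param xmin,ymax Coordinates of the north-west grid corner (meters).
#' @param cell_size Cell edge length in meters.
#' @param layers Named list of nrow x ncol matrices.
#' @param mask Logical nrow x ncol matrix; TRUE for cells inside the region.
#' @param region Optional `study_region` the stack is masked to.
#' @return A `raster_stack`.
#' @export
raster_stack <- function(xmin, ymax, cell_size, layers, mask, region = NULL) {
  dims <- unique(lapply(layers, dim))
  stopifnot(length(dims) == 1, all(dim(mask) == dims[[1]]))
  structure(list(xmin = xmin, ymax = ymax, cell_size = cell_size,
                 nrow = dims[[1]][1], ncol = dims[[1]][2],
                 layers = layers, mask = mask, region = region),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d x %d cells @ %g m, %d masked-in, layers: %s\n",
              x$nrow, x$ncol, x$cell_size, sum(x$mask),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Cell-center coordinates of a raster stack
#'
#' @param stack A `raster_stack` (or any object with the same grid fields).
#' @return List with matrices `x` and `y` of cell-center coordinates.
#' @export
cell_centers <- function(stack) {
  cs <- stack$cell_size
  x <- matrix(stack$xmin + (seq_len(stack$ncol) - 0.5) * cs,
              stack$nrow, stack$ncol, byrow = TRUE)
  y <- matrix(stack$ymax - (seq_len(stack$nrow) - 0.5) * cs,
              stack$nrow, stack$ncol)
  list(x = x, y = y)
}

# Row/column indices (1-based) of the cells containing points; NA outside grid.
cell_index <- function(stack, x, y) {
  c_ <- ceiling((x - stack$xmin) / stack$cell_size)
  r_ <- ceiling((stack$ymax - y) / stack$cell_size)
  bad <- c_ < 1 | c_ > stack$ncol | r_ < 1 | r_ > stack$nrow
  r_[bad] <- NA_integer_; c_[bad] <- NA_integer_
  list(row = r_, col = c_, lin = (c_ - 1L) * stack$nrow + r_)
}

#' Simulate a stationary Gaussian random field on a grid
#'
#' Circulant-embedding synthesis of a unit-variance field with exponential
#' correlation `exp(-3 d / range)`, so `range` is the practical correlation
#' range: the distance at which correlation has decayed to ~5% (and the
#' variogram has climbed to ~95% of its sill). Negative embedding
#' eigenvalues (possible for the exponential model on a torus) are clamped
#' to zero and the field is rescaled back to unit marginal variance.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cell_size Cell size in meters.
#' @param range Practical correlation range in meters.
#' @param seed Optional seed.
#' @return nrow x ncol numeric matrix, mean 0, variance 1.
#' @export
sim_grf <- function(nrow, ncol, cell_size, range, seed = NULL) {
  with_seed(seed, {
    M <- stats::nextn(2 * nrow, c(2, 3)); N <- stats::nextn(2 * ncol, c(2, 3))
    di <- pmin(0:(M - 1), M - (0:(M - 1))) * cell_size
    dj <- pmin(0:(N - 1), N - (0:(N - 1))) * cell_size
    d <- sqrt(outer(di^2, dj^2, `+`))
    C <- exp(-3 * d / range)
    lam <- Re(fft(C))
    lam[lam < 0] <- 0
    z <- matrix(rnorm(M * N), M, N) + 1i * matrix(rnorm(M * N), M, N)
    f <- fft(sqrt(lam) * z) / sqrt(M * N)
    fld <- Re(f)[seq_len(nrow), seq_len(ncol)]
    fld / sqrt(sum(lam) / (M * N)) # unit marginal variance after clamping
  })
}

default_field_params <- function() {
  # single-scale mosaics by default; a fine-scale component (frac_fine of
  # the variance at range_fine) can be mixed in to mimic stand-level
  # patchiness overlaying landforms
  list(
    elevation = list(mean = 240, sd = 55, range = 9000,
                     range_fine = 2500, frac_fine = 0),
    canopy    = list(mean_p = 0.60, sd_logit = 1.0, range = 7500,
                     range_fine = 2000, frac_fine = 0),
    conifer   = list(mean_p = 0.35, sd_logit = 1.2, range = 6000,
                     range_fine = 2000, frac_fine = 0)
  )
}

# unit-variance field, optionally a two-scale mixture
sim_field <- function(nr, nc, cell_size, p) {
  z <- sim_grf(nr, nc, cell_size, p$range)
  if (!is.null(p$frac_fine) && p$frac_fine > 0) {
    zf <- sim_grf(nr, nc, cell_size, p$range_fine)
    z <- sqrt(1 - p$frac_fine) * z + sqrt(p$frac_fine) * zf
  }
  z
}

#' Generate synthetic habitat rasters for a region
#'
#' Elevation is a transformed Gaussian random field; canopy and conifer
#' proportions are logistic transforms of independent fields (bounded in
#' \[0, 1\]); slope is computed from elevation by central finite differences;
#' distance-to-shore and distance-to-inland-lake are computed geometrically
#' from the region outline. The default 30 m cell size matches the resolution
#' of the land-cover and elevation products the analysis emulates.
#'
#' @param region A `study_region`.
#' @param cell_size Cell size in meters (default 30).
#' @param field_params Per-layer list of mean/variance/correlation-range
#'   settings; see `default_field_params()`.
#' @param seed Integer seed.
#' @return A `raster_stack` with layers elevation, slope, canopy, conifer,
#'   dist_shore, dist_lake.
#' @export
generate_habitat_fields <- function(region, cell_size = 30,
                                    field_params = default_field_params(),
                                    seed = 1L) {
  stopifnot(cell_size > 0)
  for (p in field_params) if (!is.null(p$range) && p$range <= 0)
    stop("correlation ranges must be positive")
  bb <- region_bbox(region)
  xmin <- bb[["xmin"]] - cell_size; ymax <- bb[["ymax"]] + cell_size
  nc <- ceiling((bb[["xmax"]] + cell_size - xmin) / cell_size)
  nr <- ceiling((ymax - (bb[["ymin"]] - cell_size)) / cell_size)
  cc <- list(
    x = matrix(xmin + (seq_len(nc) - 0.5) * cell_size, nr, nc, byrow = TRUE),
    y = matrix(ymax - (seq_len(nr) - 0.5) * cell_size, nr, nc))
  mask <- matrix(region_contains(region, as.numeric(cc$x), as.numeric(cc$y)),
                 nr, nc)
  if (!any(mask)) stop("degenerate region: no raster cells fall inside it")

  with_seed(seed, {
    fp <- field_params
    elev <- fp$elevation$mean + fp$elevation$sd *
      sim_field(nr, nc, cell_size, fp$elevation)
    canopy <- plogis(qlogis(fp$canopy$mean_p) + fp$canopy$sd_logit *
                       sim_field(nr, nc, cell_size, fp$canopy))
    conifer <- plogis(qlogis(fp$conifer$mean_p) + fp$conifer$sd_logit *
                        sim_field(nr, nc, cell_size, fp$conifer))

    # slope in degrees from central differences of elevation
    dzdx <- elev; dzdy <- elev
    dzdx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * cell_size)
    dzdx[, c(1, nc)] <- dzdx[, c(2, nc - 1)]
    dzdy[2:(nr - 1), ] <- (elev[1:(nr - 2), ] - elev[3:nr, ]) / (2 * cell_size)
    dzdy[c(1, nr), ] <- dzdy[c(2, nr - 1), ]
    slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi

    xs <- as.numeric(cc$x)[mask]; ys <- as.numeric(cc$y)[mask]
    dist_shore <- matrix(NA_real_, nr, nc)
    dist_shore[mask] <- dist_to_rings(xs, ys, region$boundary)
    dist_lake <- matrix(NA_real_, nr, nc)
    dist_lake[mask] <- if (length(region$lakes))
      dist_to_rings(xs, ys, region$lakes) else Inf

    layers <- list(elevation = elev, slope = slope, canopy = canopy,
                   conifer = conifer, dist_shore = dist_shore,
                   dist_lake = dist_lake)
    layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
    raster_stack(xmin, ymax, cell_size, layers, mask, region)
  })
}

#' Empirical isotropic variogram of a raster layer
#'
#' Support tool for validating simulated fields: semivariance of masked-in
#' cell values in distance bins, from a random subsample of cell pairs.
#'
#' @param stack A `raster_stack`.
#' @param layer Layer name.
#' @param breaks Distance-bin breaks in meters.
#' @param n_pairs Number of random cell pairs to sample.
#' @param seed Optional seed.
#' @return Data frame with bin midpoint `d` and semivariance `gamma`.
#' @export
empirical_variogram <- function(stack, layer, breaks, n_pairs = 2e5,
                                seed = NULL) {
  with_seed(seed, {
    cc <- cell_centers(stack)
    v <- stack$layers[[layer]][stack$mask]
    xs <- cc$x[stack$mask]; ys <- cc$y[stack$mask]
    i <- sample.int(length(v), n_pairs, replace = TRUE)
    j <- sample.int(length(v), n_pairs, replace = TRUE)
    d <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2)
    g <- 0.5 * (v[i] - v[j])^2
    bin <- cut(d, breaks, labels = FALSE)
    ok <- !is.na(bin)
    gamma <- tapply(g[ok], bin[ok], mean)
    mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
    data.frame(d = mid[as.integer(names(gamma))], gamma = as.numeric(gamma))
  })
}
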