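# Buffer-based extraction of habitat covariates at kill sites and
# standardization for regression.

KZ_COVARIATES <- c("canopy", "conifer", "elevation", "slope",
                   "dist_shore", "dist_lake")

#' Mean habitat covariates within a buffer around one site
#'
#' Averages each raster layer over the masked-in cells whose centers lie
#' within `diameter / 2` of the site (center-in-circle inclusion). The
#' default 100 m diameter corresponds to a 0.79 ha buffer, the scale of
#' short-range prey movement and of the chase preceding a kill; buffers
#' clipped at the coastline use only inside cells.
#'
#' @param site Length-2 numeric `(x, y)` in meters.
#' @param stack A `raster_stack`.
#' @param diameter Buffer diameter in meters (default 100).
#' @return Named numeric vector of layer means, with attributes `n_cells`
#'   and `buffer_area_ha`.
#' @export
buffer_stats <- function(site, stack, diameter = 100) {
  stopifnot(length(site) == 2, diameter > 0)
  rad <- diameter / 2
  cs <- stack$cell_size
  # candidate window of cells, then exact center-distance test
  c0 <- ceiling((site[1] - rad - stack$xmin) / cs)
  c1 <- ceiling((site[1] + rad - stack$xmin) / cs)
  r0 <- ceiling((stack$ymax - (site[2] + rad)) / cs)
  r1 <- ceiling((stack$ymax - (site[2] - rad)) / cs)
  if (c1 < 1 || c0 > stack$ncol || r1 < 1 || r0 > stack$nrow)
    stop(sprintf("buffer at (%.0f, %.0f) contains no masked-in cells",
                 site[1], site[2]))
  rs <- max(1L, r0):min(stack$nrow, r1)
  cols <- max(1L, c0):min(stack$ncol, c1)
  cx <- stack$xmin + (cols - 0.5) * cs
  cy <- stack$ymax - (rs - 0.5) * cs
  dx2 <- outer(rep(1, length(rs)), (cx - site[1])^2)
  dy2 <- outer((cy - site[2])^2, rep(1, length(cols)))
  inside <- (dx2 + dy2 <= rad^2) & stack$mask[rs, cols, drop = FALSE]
  if (!any(inside))
    stop(sprintf("buffer at (%.0f, %.0f) contains no masked-in cells",
                 site[1], site[2]))
  out <- vapply(stack$layers, function(m) mean(m[rs, cols, drop = FALSE][inside]),
                numeric(1))
  attr(out, "n_cells") <- sum(inside)
  attr(out, "buffer_area_ha") <- pi * rad^2 / 1e4
  out
}

#' Build the habitat design matrix for a set of sites
#'
#' @param points A `point_pattern`.
#' @param stack A `raster_stack` holding the six covariate layers.
#' @param diameter Buffer diameter in meters.
#' @param fallback_nearest When TRUE (default), a site whose buffer holds no
#'   masked-in cell centers (possible right at the coastline, or on grids
#'   coarser than the buffer) takes the values of the nearest masked-in cell
#'   instead of failing.
#' @return A `habitat_matrix`: data frame of per-site covariate means with
#'   attributes `standardized`, `diameter`, `buffer_area_ha`, and the site
#'   coordinates and labels.
#' @export
habitat_matrix <- function(points, stack, diameter = 100,
                           fallback_nearest = TRUE) {
  cc <- cell_centers(stack)
  cxm <- cc$x[stack$mask]; cym <- cc$y[stack$mask]
  nearest_cell_values <- function(x, y) {
    i <- which.min((cxm - x)^2 + (cym - y)^2)
    vapply(stack$layers, function(m) m[stack$mask][i], numeric(1))
  }
  m <- t(vapply(seq_len(points$n), function(i) {
    v <- tryCatch(
      buffer_stats(c(points$x[i], points$y[i]), stack, diameter),
      error = function(e) if (fallback_nearest)
        nearest_cell_values(points$x[i], points$y[i]) else stop(e))
    v[KZ_COVARIATES]
  }, numeric(length(KZ_COVARIATES))))
  colnames(m) <- KZ_COVARIATES
  df <- as.data.frame(m)
  structure(df, class = c("habitat_matrix", "data.frame"),
            standardized = FALSE, diameter = diameter,
            buffer_area_ha = pi * (diameter / 2)^2 / 1e4,
            x = points$x, y = points$y, labels = points$labels)
}

#' Standardize habitat covariates to mean 0, sd 1
#'
#' Columns are z-scored with the sample (n - 1) standard deviation; the
#' means and sds are stored for back-transformation. Standardization is
#' intended to run on the pooled site set of both prey classes so that
#' standardized coefficients are comparable between the per-class models.
#'
#' @param matrix A `habitat_matrix` (>= 2 rows, no constant columns).
#' @return The standardized `habitat_matrix` with attributes `column_means`
#'   and `column_sds`.
#' @export
standardize <- function(matrix) {
  stopifnot(nrow(matrix) >= 2)
  if (isTRUE(attr(matrix, "standardized")))
    stop("matrix is already standardized")
  mu <- vapply(matrix, mean, numeric(1))
  s <- vapply(matrix, sd, numeric(1))
  if (any(s == 0))
    stop("degenerate covariate (constant column): ",
         paste(names(s)[s == 0], collapse = ", "))
  out <- as.data.frame(scale(as.matrix(matrix), center = mu, scale = s))
  attributes(out) <- c(attributes(out),
                       attributes(matrix)[c("diameter", "buffer_area_ha",
                                            "x", "y", "labels")])
  structure(out, class = c("habitat_matrix", "data.frame"),
            standardized = TRUE, column_means = mu, column_sds = s)
}

#' Invert a standardization
#'
#' @param matrix A standardized `habitat_matrix`.
#' @return The matrix on its original scale.
#' @export
unstandardize <- function(matrix) {
  if (!isTRUE(attr(matrix, "standardized"))) stop("matrix is not standardized")
  mu <- attr(matrix, "column_means"); s <- attr(matrix, "column_sds")
  out <- sweep(sweep(as.matrix(matrix), 2, s, `*`), 2, mu, `+`)
  out <- as.data.frame(out)
  attributes(out) <- c(attributes(out),
                       attributes(matrix)[c("diameter", "buffer_area_ha",
                                            "x", "y", "labels")])
  structure(out, class = c("habitat_matrix", "data.frame"),
            standardized = FALSE)
}
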