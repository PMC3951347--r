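# Point patterns of kill sites and the class-structured simulator.

#' Construct a point pattern
#'
#' @param x,y Coordinates in meters.
#' @param labels Per-point class labels (recycled if length 1).
#' @param region The `study_region` the points live in.
#' @return A `point_pattern`.
#' @export
point_pattern <- function(x, y, labels = "generic", region) {
  n <- length(x)
  stopifnot(n >= 1, length(y) == n)
  if (length(labels) == 1) labels <- rep(labels, n)
  stopifnot(length(labels) == n)
  if (!all(region_contains(region, x, y)))
    stop("all points must lie inside the region")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 labels = as.character(labels), region = region, n = n),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points (%s)\n", x$n,
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Subset a point pattern by class label
#'
#' @param pattern A `point_pattern`.
#' @param label Class label to keep.
#' @return A `point_pattern` with only that class.
#' @export
subset_pattern <- function(pattern, label) {
  keep <- pattern$labels == label
  if (!any(keep)) stop("no points with label '", label, "'")
  point_pattern(pattern$x[keep], pattern$y[keep], label, pattern$region)
}

#' Ground-truth settings for the kill-site simulator
#'
#' @param intensity_coefficients Named or positional numeric vector of six
#'   log-linear coefficients over the standardized covariates (elevation,
#'   slope, canopy, conifer, dist_shore, dist_lake).
#' @param n_points Number of points to generate.
#' @param cluster_params Optional list with `parent_intensity` (parents per
#'   square meter), `offspring_mean` (informational; the point count is fixed
#'   by `n_points`), `sigma` (Gaussian offspring dispersion, meters),
#'   `parent_uniform` (TRUE places parents by CSR instead of by the habitat
#'   intensity; default FALSE), `thin_exponent` (exponent tempering the
#'   offspring habitat thinning; default 1), `tightness` (exponent shrinking
#'   sigma in good habitat; default 0) and `mass_exponent` (habitat weighting
#'   of cluster masses; default 0, i.e. equal expected masses). NULL
#'   disables clustering.
#' @param seed Integer seed.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(intensity_coefficients, n_points, cluster_params = NULL,
                      seed = 1L) {
  stopifnot(length(intensity_coefficients) == 6, n_points >= 1)
  if (!is.null(cluster_params)) stopifnot(cluster_params$sigma > 0)
  structure(list(intensity_coefficients = intensity_coefficients,
                 n_points = as.integer(n_points),
                 cluster_params = cluster_params, seed = as.integer(seed)),
            class = "sim_truth")
}

# Log-linear intensity over standardized covariates, evaluated per raster
# cell. Returns a matrix with NA outside the mask.
intensity_surface <- function(fields, beta) {
  z <- 0
  nms <- c("elevation", "slope", "canopy", "conifer", "dist_shore", "dist_lake")
  for (k in seq_along(nms)) {
    v <- fields$layers[[nms[k]]]
    mu <- mean(v[fields$mask]); s <- sd(v[fields$mask])
    if (s == 0) s <- 1
    z <- z + beta[k] * (v - mu) / s
  }
  lam <- exp(z)
  lam[!fields$mask] <- NA_real_
  lam
}

#' Simulate kill sites from a log-linear habitat intensity
#'
#' Points are drawn from an inhomogeneous process whose intensity is
#' log-linear in the six standardized habitat covariates, by thinning:
#' candidate locations are sampled uniformly in the region and accepted with
#' probability intensity / (1.001 x max cell intensity). With
#' `cluster_params` set, a Thomas-style overlay is applied: parent locations
#' are drawn from the same inhomogeneous intensity (or uniformly), each of
#' the `n_points` final points is assigned to a parent (uniformly, or
#' weighted by habitat quality via `mass_exponent`), and its position is
#' drawn exactly from the discretized product of the Gaussian displacement
#' kernel (sd `sigma`, optionally habitat-scaled via `tightness`) and the
#' habitat intensity over the masked cells within 3 sigma of the parent.
#'
#' @param fields A `raster_stack` of habitat layers.
#' @param truth A `sim_truth`.
#' @param class_label Label attached to the generated points.
#' @return A `point_pattern`.
#' @export
simulate_kill_sites <- function(fields, truth, class_label = "generic") {
  region <- fields$region
  stopifnot(!is.null(region))
  lam <- intensity_surface(fields, truth$intensity_coefficients)
  lmax <- max(lam, na.rm = TRUE)
  if (!is.finite(lmax) || lmax <= 0)
    stop("sampling failure: intensity is numerically zero everywhere")
  envelope <- lmax * 1.001

  draw_inhom <- function(m) {
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < m) {
      cand <- sample_csr(region, max(4 * m, 256))
      idx <- cell_index(fields, cand[, 1], cand[, 2])
      li <- lam[idx$lin]
      li[is.na(li)] <- 0 # candidate in an unmasked sliver cell
      acc <- runif(nrow(cand)) < li / envelope
      out <- rbind(out, cand[acc, , drop = FALSE])
    }
    out[seq_len(m), , drop = FALSE]
  }

  with_seed(truth$seed, {
    n <- truth$n_points
    cp <- truth$cluster_params
    if (is.null(cp)) {
      pts <- draw_inhom(n)
    } else {
      n_par <- max(1L, rpois(1, cp$parent_intensity * region$area))
      parents <- if (isTRUE(cp$parent_uniform)) sample_csr(region, n_par)
                 else draw_inhom(n_par)
      gam <- if (is.null(cp$thin_exponent)) 1 else cp$thin_exponent
      tgt <- if (is.null(cp$tightness)) 0 else cp$tightness
      # cluster tightness tracks habitat quality: sigma shrinks (tempered
      # power law, clamped to [sigma/3, 3 sigma]) where the intensity at the
      # parent is high, so preferred habitat hosts denser - not more massive -
      # clusters; with tightness = 0 all clusters share sigma
      # habitat quality of each cluster: mean intensity over the footprint
      # (cells within one sigma of the parent), a stabler summary than the
      # parent's single cell
      ccf <- cell_centers(fields)
      lam_par <- vapply(seq_len(n_par), function(k) {
        near <- fields$mask &
          (ccf$x - parents[k, 1])^2 + (ccf$y - parents[k, 2])^2 <= cp$sigma^2
        if (!any(near)) return(NA_real_)
        mean(lam[near], na.rm = TRUE)
      }, numeric(1))
      lam_par[is.na(lam_par) | lam_par <= 0] <- min(lam, na.rm = TRUE)
      sig_k <- cp$sigma * (lam_par / stats::median(lam_par))^(-tgt)
      sig_k <- pmin(pmax(sig_k, cp$sigma / 3), 3 * cp$sigma)
      # offspring positions are drawn exactly from the discretized product
      # density Gaussian(distance to parent; sigma_k) x intensity^gamma over
      # the masked cells within 3 sigma of the parent (then jittered within
      # the cell), so within-cluster placement tracks the covariates;
      # thin_exponent < 1 tempers the preference
      cc <- cell_centers(fields)
      cs <- fields$cell_size
      # optional habitat-weighted cluster masses: assignment probability
      # proportional to intensity^mass_exponent at the parent (0 = uniform)
      mex <- if (is.null(cp$mass_exponent)) 0 else cp$mass_exponent
      wpar <- if (mex > 0) lam_par^mex else rep(1, n_par)
      assign_ <- sample.int(n_par, n, replace = TRUE, prob = wpar)
      pts <- matrix(NA_real_, n, 2)
      for (k in seq_len(n_par)) {
        take <- which(assign_ == k)
        if (!length(take)) next
        d2 <- (cc$x - parents[k, 1])^2 + (cc$y - parents[k, 2])^2
        near <- which(fields$mask & d2 <= (3 * sig_k[k])^2)
        if (!length(near)) { # parent in a coastal sliver: keep it in place
          pts[take, 1] <- parents[k, 1]; pts[take, 2] <- parents[k, 2]
          next
        }
        lw <- gam * log(lam[near]) - d2[near] / (2 * sig_k[k]^2)
        w <- exp(lw - max(lw))
        cells_k <- near[sample.int(length(near), length(take), replace = TRUE,
                                   prob = w)]
        px <- cc$x[cells_k] + runif(length(take), -cs / 2, cs / 2)
        py <- cc$y[cells_k] + runif(length(take), -cs / 2, cs / 2)
        # jittered positions in edge cells may cross the coastline; snap
        # those back to the (inside) cell center
        out <- !region_contains(region, px, py)
        px[out] <- cc$x[cells_k][out]; py[out] <- cc$y[cells_k][out]
        pts[take, 1] <- px; pts[take, 2] <- py
      }
    }
    point_pattern(pts[, 1], pts[, 2], class_label, region)
  })
}
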