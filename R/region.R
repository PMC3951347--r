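# Study region: a bounded planar island polygon, optionally with inner lakes.

#' Construct a study region
#'
#' @param boundary List of boundary rings (n x 2 matrices, meters) or a single
#'   matrix.
#' @param lakes List of inner-lake rings (may be empty).
#' @return A `study_region`: list with `boundary`, `lakes` and `area` (square
#'   meters; boundary area minus lake area).
#' @export
study_region <- function(boundary, lakes = list()) {
  if (is.matrix(boundary)) boundary <- list(boundary)
  stopifnot(length(boundary) >= 1)
  a_b <- sum(vapply(boundary, function(r) abs(ring_area(r)), numeric(1)))
  a_l <- if (length(lakes)) sum(vapply(lakes, function(r) abs(ring_area(r)), numeric(1))) else 0
  area <- a_b - a_l
  if (!is.finite(area) || area <= 0) stop("region must have positive area")
  structure(list(boundary = boundary, lakes = lakes, area = area),
            class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("study_region: area %.1f km2, %d boundary ring(s), %d lake(s)\n",
              x$area / 1e6, length(x$boundary), length(x$lakes)))
  invisible(x)
}

#' Generate a synthetic elongated island
#'
#' Builds the island as a smoothed random radial perturbation of an ellipse:
#' the radius at angle theta is modulated by a low-order random harmonic
#' series, which keeps the ring star-shaped (hence simple) while producing an
#' irregular coastline. The polygon is rescaled so that its land area (boundary
#' minus lakes) matches `target_area` exactly; 1-3 small inner lakes are
#' placed along the long axis. The default area matches a ~544 km2 island.
#'
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param target_area Island land area in square meters (default 544e6).
#' @param aspect Ratio of the long to the short semi-axis (>= 3 keeps the
#'   island elongated).
#' @param n_vertices Number of boundary vertices.
#' @return A `study_region`.
#' @export
generate_island <- function(seed, target_area = 544e6, aspect = 3.5,
                            n_vertices = 192) {
  if (!is.numeric(target_area) || target_area <= 0)
    stop("target_area must be positive")
  with_seed(seed, {
    theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    # low-order harmonic radial noise, amplitude bounded so r stays positive
    nh <- 5
    amp <- runif(nh, 0, 0.18) / seq_len(nh)
    phs <- runif(nh, 0, 2 * pi)
    r <- rep(1, n_vertices)
    for (k in seq_len(nh)) r <- r + amp[k] * cos(k * theta + phs[k])
    b <- sqrt(target_area / (pi * aspect)) # ellipse semi-minor, pre-scaling
    a <- aspect * b
    ring <- cbind(a * r * cos(theta), b * r * sin(theta))

    # lakes: 1-3 small circles strung along the long axis, strictly inland
    n_lakes <- sample.int(3, 1)
    lakes <- list()
    boundary_tmp <- list(ring)
    for (i in seq_len(n_lakes)) {
      for (try in 1:50) {
        cx <- runif(1, -0.6 * a, 0.6 * a)
        cy <- runif(1, -0.4 * b, 0.4 * b)
        rad <- runif(1, 400, 900)
        phi <- 2 * pi * (seq_len(48) - 1) / 48
        lring <- cbind(cx + rad * cos(phi), cy + rad * sin(phi))
        # strictly inside: every vertex inside the boundary with margin,
        # and not overlapping an existing lake
        inside <- all(cpp_in_region(lring[, 1], lring[, 2], boundary_tmp, list()))
        margin <- min(cpp_dist_to_ring(lring[, 1], lring[, 2], ring)) > 250
        clear <- !length(lakes) ||
          all(vapply(lakes, function(l)
            sqrt((l$c[1] - cx)^2 + (l$c[2] - cy)^2) > (l$r + rad + 500),
            logical(1)))
        if (inside && margin && clear) {
          lakes[[length(lakes) + 1]] <- list(ring = lring, c = c(cx, cy), r = rad)
          break
        }
      }
    }
    lake_rings <- lapply(lakes, `[[`, "ring")

    # uniform rescale of coastline and lakes together so the land area
    # (boundary minus lakes) hits target_area exactly; a uniform scale
    # preserves lake containment
    a_l <- if (length(lake_rings))
      sum(vapply(lake_rings, function(r2) abs(ring_area(r2)), numeric(1))) else 0
    s <- sqrt(target_area / (abs(ring_area(ring)) - a_l))
    ring <- ring * s
    lake_rings <- lapply(lake_rings, function(r2) r2 * s)
    study_region(ring, lake_rings)
  })
}
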