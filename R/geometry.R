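# Planar polygon utilities shared by the region, raster and point-pattern
# code. Rings are n x 2 matrices of vertex coordinates in meters, not closed
# (the last vertex is implicitly joined to the first).

#' Signed area of a planar ring (shoelace formula)
#'
#' Positive for counter-clockwise rings, negative for clockwise.
#'
#' @param ring n x 2 numeric matrix of vertices (meters), not closed.
#' @return Signed area in square meters.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Test points against a polygonal region
#'
#' Vectorized point-in-polygon with holes: a point is inside when it falls
#' within a boundary ring and within no lake ring.
#'
#' @param region A `study_region`.
#' @param x,y Point coordinates (meters).
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y) {
  cpp_in_region(as.numeric(x), as.numeric(y), region$boundary, region$lakes)
}

#' Bounding box of a region
#'
#' @param region A `study_region`.
#' @return Named numeric vector `(xmin, xmax, ymin, ymax)`.
#' @export
region_bbox <- function(region) {
  xs <- unlist(lapply(region$boundary, function(r) r[, 1]))
  ys <- unlist(lapply(region$boundary, function(r) r[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Minimum distance from points to the outline of a set of rings.
dist_to_rings <- function(x, y, rings) {
  d <- rep(Inf, length(x))
  for (r in rings) d <- pmin(d, cpp_dist_to_ring(as.numeric(x), as.numeric(y), r))
  d
}

#' Sample a homogeneous (CSR) point pattern in a region
#'
#' Rejection sampling from the bounding box; the binomial-process analogue of
#' complete spatial randomness conditioned on `n` points.
#'
#' @param region A `study_region`.
#' @param n Number of points.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return n x 2 matrix of coordinates.
#' @export
sample_csr <- function(region, n, seed = NULL) {
  with_seed(seed, {
    bb <- region_bbox(region)
    out <- matrix(numeric(0), ncol = 2)
    # acceptance rate = area / bbox area; draw in batches
    rate <- max(region$area / ((bb[2] - bb[1]) * (bb[4] - bb[3])), 0.05)
    while (nrow(out) < n) {
      m <- ceiling((n - nrow(out)) / rate * 1.2) + 16
      px <- runif(m, bb[1], bb[2]); py <- runif(m, bb[3], bb[4])
      ok <- region_contains(region, px, py)
      out <- rbind(out, cbind(px[ok], py[ok]))
    }
    out[seq_len(n), , drop = FALSE]
  })
}
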