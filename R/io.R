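# Readers and writers for the package's external formats: GeoJSON for
# regions, points and core polygons; CSV for point tables; ESRI ASCII grids
# for raster layers (the plain-text raster interchange format).

ring_closed <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Write a study region to GeoJSON
#'
#' The island is written as a single Polygon feature whose first ring is the
#' boundary and subsequent rings are inner lakes.
#'
#' @param region A `study_region`.
#' @param path Output file.
#' @export
write_region_geojson <- function(region, path) {
  rings <- c(lapply(region$boundary, ring_closed),
             lapply(region$lakes, ring_closed))
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(area_m2 = region$area, n_lakes = length(region$lakes)),
    geometry = list(type = "Polygon",
                    coordinates = lapply(rings, function(r)
                      lapply(seq_len(nrow(r)), function(i) r[i, ]))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study region from GeoJSON
#'
#' Expects a Polygon (optionally inside a Feature/FeatureCollection); the
#' first ring is the boundary, the rest are lakes.
#'
#' @param path GeoJSON file.
#' @return A `study_region`.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- gj
  if (!is.null(gj$features)) geom <- gj$features[[1]]$geometry
  if (!is.null(geom$geometry)) geom <- geom$geometry
  if (is.null(geom$type) || geom$type != "Polygon")
    stop("expected a Polygon geometry in ", path)
  rings <- lapply(geom$coordinates, function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    m[-nrow(m), , drop = FALSE] # drop closing vertex
  })
  study_region(rings[[1]], rings[-1])
}

#' Write a point pattern to CSV (columns x, y, class)
#'
#' @param pattern A `point_pattern`.
#' @param path Output file.
#' @export
write_points_csv <- function(pattern, path) {
  write.csv(data.frame(x = pattern$x, y = pattern$y, class = pattern$labels),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a point pattern from CSV
#'
#' The file must have numeric `x` and `y` columns and a `class` column; a
#' malformed row fails with the file and line number.
#'
#' @param path CSV file.
#' @param region The `study_region` the points must fall in.
#' @return A `point_pattern`.
#' @export
read_points_csv <- function(path, region) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "class")
  if (!all(need %in% names(df)))
    stop("malformed point file ", path, ": needs columns x, y, class")
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed point file ", path, ": non-numeric ", col,
           " at line ", bad[1] + 1L)
    if (anyNA(v))
      stop("malformed point file ", path, ": missing ", col,
           " at line ", which(is.na(v))[1] + 1L)
    df[[col]] <- v
  }
  point_pattern(df$x, df$y, df$class, region)
}

#' Write points to GeoJSON
#'
#' @param pattern A `point_pattern`.
#' @param path Output file.
#' @export
write_points_geojson <- function(pattern, path) {
  feats <- lapply(seq_len(pattern$n), function(i) list(
    type = "Feature", properties = list(class = pattern$labels[i]),
    geometry = list(type = "Point",
                    coordinates = c(pattern$x[i], pattern$y[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write core-area polygons to GeoJSON
#'
#' Each ring becomes a Polygon feature tagged with its component id and
#' signed area (negative areas are holes).
#'
#' @param core A `core_area`.
#' @param path Output file.
#' @export
write_core_geojson <- function(core, path) {
  feats <- lapply(core$polygons, function(pg) list(
    type = "Feature",
    properties = list(component = unname(pg$component), area_m2 = pg$area),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(
                      seq_len(nrow(pg$ring) + 1), function(i) {
                        r <- ring_closed(pg$ring); r[i, ]
                      })))))
  jsonlite::write_json(list(
    type = "FeatureCollection",
    properties = list(percentile = core$percentile,
                      total_area_m2 = core$total_area,
                      n_polygons = core$n_polygons),
    features = feats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write one raster layer as an ESRI ASCII grid
#'
#' @param stack A `raster_stack` (or `kde_surface`).
#' @param layer Layer name, or "density" for a surface.
#' @param path Output file.
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_ascii_grid <- function(stack, layer, path, nodata = -9999) {
  m <- if (!is.null(stack$layers)) stack$layers[[layer]] else stack[[layer]]
  stopifnot(is.matrix(m))
  m[is.na(m)] <- nodata
  yll <- stack$ymax - stack$nrow * stack$cell_size
  hdr <- c(sprintf("ncols %d", stack$ncol), sprintf("nrows %d", stack$nrow),
           sprintf("xllcorner %.6f", stack$xmin),
           sprintf("yllcorner %.6f", yll),
           sprintf("cellsize %.6f", stack$cell_size),
           sprintf("NODATA_value %g", nodata))
  writeLines(c(hdr, apply(m, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Grid file.
#' @return List with `xmin`, `ymax`, `cell_size`, `nrow`, `ncol`, `values`
#'   matrix (NA where nodata).
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  hv <- setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                 tolower(vapply(hdr, `[[`, character(1), 1)))
  nr <- as.integer(hv[["nrows"]]); ncl <- as.integer(hv[["ncols"]])
  vals <- scan(text = paste(ln[-(1:6)], collapse = " "), quiet = TRUE)
  m <- matrix(vals, nr, ncl, byrow = TRUE)
  m[m == hv[["nodata_value"]]] <- NA
  list(xmin = hv[["xllcorner"]],
       ymax = hv[["yllcorner"]] + nr * hv[["cellsize"]],
       cell_size = hv[["cellsize"]], nrow = nr, ncol = ncl, values = m)
}
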