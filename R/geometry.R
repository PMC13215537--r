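#' Geometry helpers for the %TOC sample filters
#'
#' All coordinates are planar, in a projected equal-area CRS (metres;
#' EPSG:3035 for the Northwest European Shelf). Distances are Euclidean,
#' which differs negligibly from geodesic distance at the <= 5 km scales the
#' coastal filter uses.
#'
#' @name geometry
#' @keywords internal
NULL

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each point to any segment of the
#' polyline (not just its vertices).
#'
#' @param x,y Numeric vectors of point coordinates (metres).
#' @param line Two-column numeric matrix of polyline vertices (metres).
#' @return Numeric vector of distances in metres.
#' @export
dist_to_polyline <- function(x, y, line) {
  stopifnot(is.matrix(line), ncol(line) == 2, nrow(line) >= 2,
            length(x) == length(y))
  best <- rep(Inf, length(x))
  for (i in seq_len(nrow(line) - 1)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1, 1]; by <- line[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
    d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Build a substrate polygon map
#'
#' @param polygon_id Character vector of polygon identifiers.
#' @param substrate_class Character vector of classes (`"sand"`, `"coarse"`,
#'   `"mixed"`, `"mud"`, `"other"`).
#' @param rings List of closed two-column matrices (first vertex repeated
#'   last), one exterior ring per polygon, in metres.
#' @return A `substrate_map` tibble with a `ring` list-column.
#' @export
substrate_map <- function(polygon_id, substrate_class, rings) {
  out <- tibble::tibble(polygon_id = polygon_id,
                        substrate_class = substrate_class,
                        ring = rings)
  for (i in seq_len(nrow(out))) validate_ring(out$ring[[i]], out$polygon_id[i])
  class(out) <- c("substrate_map", class(out))
  out
}

validate_ring <- function(ring, id) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4 ||
      any(!is.finite(ring)) ||
      !isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
    rlang::abort(paste0("invalid polygon geometry (id ", id,
                        "): need a closed finite ring of >= 4 vertices"))
  }
  invisible(ring)
}

#' Test points against one polygon ring
#'
#' @param x,y Point coordinates (metres).
#' @param ring Closed two-column matrix.
#' @return Logical vector, TRUE where the point is inside.
#' @export
points_in_ring <- function(x, y, ring) {
  validate_ring(ring, "<anonymous>")
  # in.out expects the boundary without enforced closure; it handles both
  mgcv::in.out(ring, cbind(x, y))
}

#' Write / read a substrate map as GeoJSON
#'
#' FeatureCollection of Polygon features with a `substrate_class` property;
#' coordinates in the projected CRS (EPSG:3035 metres).
#'
#' @param map A [substrate_map()].
#' @param path GeoJSON file path.
#' @return `write_substrate_geojson()` returns `path` invisibly;
#'   `read_substrate_geojson()` returns a `substrate_map`.
#' @export
write_substrate_geojson <- function(map, path) {
  features <- lapply(seq_len(nrow(map)), function(i) {
    ring <- map$ring[[i]]
    list(
      type = "Feature",
      properties = list(polygon_id = map$polygon_id[i],
                        substrate_class = map$substrate_class[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(j) unname(ring[j, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_substrate_geojson
#' @export
read_substrate_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  ids <- character(); classes <- character(); rings <- list()
  for (f in fc$features) {
    ids <- c(ids, f$properties$polygon_id)
    classes <- c(classes, f$properties$substrate_class)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    rings <- c(rings, list(ring))
  }
  substrate_map(ids, classes, rings)
}

#' Write / read a coastline as GeoJSON
#'
#' Single LineString feature in the projected CRS.
#'
#' @param coastline Two-column matrix of vertices (metres).
#' @param path GeoJSON file path.
#' @return `write_coastline_geojson()` returns `path` invisibly;
#'   `read_coastline_geojson()` returns the vertex matrix.
#' @export
write_coastline_geojson <- function(coastline, path) {
  stopifnot(is.matrix(coastline), ncol(coastline) == 2)
  fc <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(name = "coastline"),
    geometry = list(
      type = "LineString",
      coordinates = lapply(seq_len(nrow(coastline)),
                           function(j) unname(coastline[j, ]))
    )
  )))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coastline_geojson
#' @export
read_coastline_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  coords <- fc$features[[1]]$geometry$coordinates
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}
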