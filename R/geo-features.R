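# Nearest-distance covariates to road and waterway polyline networks.
#
# All distances are planar Euclidean meters. Real inputs must therefore be
# supplied in a projected CRS; geodesic handling is deliberately out of
# scope. Vector data is exchanged as GeoJSON LineString/MultiLineString
# collections (the one plain-text vector format the toolchain reads and
# writes without a GIS stack).

#' Create an infrastructure polyline set
#'
#' @param lines List of numeric matrices, each with >= 2 rows of `(x, y)`
#'   vertices in meters.
#' @param kind `"road"` or `"water"`.
#' @return An `infrastructure_set` with a precomputed segment table.
#' @export
infrastructure_set <- function(lines, kind = c("road", "water")) {
  kind <- match.arg(kind)
  if (!is.list(lines) || length(lines) == 0L)
    stopf("`lines` must be a non-empty list of vertex matrices")
  segs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- lines[[i]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 2L)
      stopf("polyline %d must be a matrix with 2 columns and >= 2 vertices", i)
    if (!all(is.finite(m))) stopf("polyline %d has non-finite coordinates", i)
    n <- nrow(m)
    segs[[i]] <- cbind(m[-n, 1], m[-n, 2], m[-1, 1], m[-1, 2])
  }
  segs <- do.call(rbind, segs)
  structure(list(lines = lines, kind = kind, segments = segs),
            class = "infrastructure_set")
}

#' @export
print.infrastructure_set <- function(x, ...) {
  cat(sprintf("<infrastructure_set> kind=%s, %d polylines, %d segments\n",
              x$kind, length(x$lines), nrow(x$segments)))
  invisible(x)
}

#' Distance from a point to the nearest infrastructure polyline
#'
#' Minimum Euclidean point-to-segment distance over all segments of all
#' polylines in the set.
#'
#' @param point_xy Numeric `c(x, y)` in meters.
#' @param infra An [infrastructure_set()].
#' @return Distance in meters.
#' @export
nearest_distance <- function(point_xy, infra) {
  d <- nearest_distance_many(matrix(point_xy, nrow = 1), infra)
  d[[1]]
}

#' Distances from many points to the nearest polyline
#'
#' @param points Numeric matrix with columns `(x, y)` in meters.
#' @param infra An [infrastructure_set()].
#' @return Numeric vector of distances (meters), one per point row.
#' @export
nearest_distance_many <- function(points, infra) {
  if (!inherits(infra, "infrastructure_set"))
    stopf("`infra` must be an infrastructure_set")
  s <- infra$segments
  if (is.null(s) || nrow(s) == 0L) stopf("empty infrastructure set: distance undefined")
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  out <- rep(Inf, n)
  # chunk over segments to bound the n_points x n_segments working set
  chunk <- max(1L, floor(4e6 / max(n, 1L)))
  for (k0 in seq(1L, nrow(s), by = chunk)) {
    k1 <- min(k0 + chunk - 1L, nrow(s))
    ax <- s[k0:k1, 1]; ay <- s[k0:k1, 2]
    bx <- s[k0:k1, 3]; by <- s[k0:k1, 4]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    # outer products: rows = points, cols = segments
    px <- points[, 1]; py <- points[, 2]
    wx <- outer(px, ax, "-"); wy <- outer(py, ay, "-")
    tnum <- sweep(wx, 2, vx, "*") + sweep(wy, 2, vy, "*")
    tt <- sweep(tnum, 2, pmax(len2, .Machine$double.eps), "/")
    tt <- clamp(tt, 0, 1)
    tt[, len2 == 0] <- 0  # degenerate segment: nearest point is the vertex
    dx <- wx - sweep(tt, 2, vx, "*")
    dy <- wy - sweep(tt, 2, vy, "*")
    d2 <- dx^2 + dy^2
    out <- pmin(out, if (ncol(d2) > 1L) apply(d2, 1, min) else d2[, 1])
  }
  sqrt(out)
}

#' Per-tile nearest-road and nearest-water distances
#'
#' Distances are measured from tile centers, matching the point semantics of
#' the settlement locations.
#'
#' @param tiles Data frame / tibble with columns `tile_id`, `x_m`, `y_m`.
#' @param roads,waters [infrastructure_set()] objects.
#' @return Tibble `(tile_id, d_road_m, d_water_m)` in input order.
#' @export
compute_distance_features <- function(tiles, roads, waters) {
  need <- c("tile_id", "x_m", "y_m")
  if (!all(need %in% names(tiles)))
    stopf("`tiles` must have columns %s", paste(need, collapse = ", "))
  bad <- !is.finite(tiles$x_m) | !is.finite(tiles$y_m)
  if (any(bad))
    stopf("missing/non-finite coordinates for tile(s): %s",
          paste(utils::head(tiles$tile_id[bad], 5), collapse = ", "))
  pts <- cbind(tiles$x_m, tiles$y_m)
  tibble::tibble(
    tile_id = tiles$tile_id,
    d_road_m = nearest_distance_many(pts, roads),
    d_water_m = nearest_distance_many(pts, waters)
  )
}

# ---- GeoJSON I/O -----------------------------------------------------------

#' Write an infrastructure set as GeoJSON
#' @param infra An [infrastructure_set()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_infrastructure_geojson <- function(infra, path) {
  feats <- lapply(seq_along(infra$lines), function(i) {
    m <- infra$lines[[i]]
    list(
      type = "Feature",
      properties = list(kind = infra$kind, id = i),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(m)), function(r) c(m[r, 1], m[r, 2]))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read LineString/MultiLineString GeoJSON as an infrastructure set
#' @param path Path to a GeoJSON FeatureCollection.
#' @param kind `"road"` or `"water"`.
#' @return An [infrastructure_set()].
#' @export
read_infrastructure_geojson <- function(path, kind = c("road", "water")) {
  kind <- match.arg(kind)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$features)) stopf("%s: not a GeoJSON FeatureCollection", path)
  lines <- list()
  for (f in j$features) {
    g <- f$geometry
    coords_to_mat <- function(cc)
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    if (identical(g$type, "LineString")) {
      lines[[length(lines) + 1L]] <- coords_to_mat(g$coordinates)
    } else if (identical(g$type, "MultiLineString")) {
      for (part in g$coordinates)
        lines[[length(lines) + 1L]] <- coords_to_mat(part)
    } else {
      stopf("unsupported geometry type '%s' (expected LineString/MultiLineString)", g$type)
    }
  }
  infrastructure_set(lines, kind)
}

#' Write distance records to CSV
#' @param records Tibble from [compute_distance_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
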