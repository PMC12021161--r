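# Tile grids over a region, tile extraction, and the spatial-resolution
# degradation protocol.
#
# Coordinates are scene-local planar meters with the origin at the raster's
# top-left corner and y increasing southward (image convention). Tiles are
# half-open squares [x, x + tile) x [y, y + tile) so adjacent tiles share no
# pixels.

#' Build a non-overlapping tile grid over a rectangular region
#'
#' The grid uses the field-standard 128 m x 128 m tile footprint by default.
#' The last row/column may overhang the region boundary; overhanging tiles
#' are kept (and later zero-padded) so the grid always covers the region.
#'
#' @param region_bounds Either `c(width_m, height_m)` (origin at 0,0) or
#'   `c(xmin, ymin, xmax, ymax)` in meters.
#' @param tile_size_m Tile edge length in meters (default 128).
#' @param resolution_m_per_px Ground sampling distance of the raster the grid
#'   will index, in meters per pixel.
#' @return A `tile_grid` object with fields `origin_xy`, `tile_size_m`,
#'   `n_cols`, `n_rows`, `resolution_m_per_px`, `region_width_m`,
#'   `region_height_m`.
#' @examples
#' g <- build_tile_grid(c(90000, 60000), tile_size_m = 128,
#'                      resolution_m_per_px = 0.5)
#' n_tiles(g)  # 330176 candidate tiles over 5,400 km^2
#' @export
build_tile_grid <- function(region_bounds, tile_size_m = 128,
                            resolution_m_per_px = 0.5) {
  check_number(tile_size_m, "tile_size_m", positive = TRUE)
  check_number(resolution_m_per_px, "resolution_m_per_px", positive = TRUE)
  if (length(region_bounds) == 2L) {
    origin <- c(0, 0)
    width <- region_bounds[[1]]
    height <- region_bounds[[2]]
  } else if (length(region_bounds) == 4L) {
    origin <- region_bounds[1:2]
    width <- region_bounds[[3]] - region_bounds[[1]]
    height <- region_bounds[[4]] - region_bounds[[2]]
  } else {
    stopf("`region_bounds` must have length 2 (width, height) or 4 (xmin, ymin, xmax, ymax)")
  }
  if (width <= 0 || height <= 0) stopf("region width and height must be > 0")
  structure(
    list(
      origin_xy = as.numeric(origin),
      tile_size_m = as.numeric(tile_size_m),
      n_cols = as.integer(ceiling(width / tile_size_m)),
      n_rows = as.integer(ceiling(height / tile_size_m)),
      resolution_m_per_px = as.numeric(resolution_m_per_px),
      region_width_m = as.numeric(width),
      region_height_m = as.numeric(height)
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %d x %d tiles of %g m (%g m/px), region %g x %g m\n",
    x$n_cols, x$n_rows, x$tile_size_m, x$resolution_m_per_px,
    x$region_width_m, x$region_height_m))
  invisible(x)
}

#' Total number of tiles in a grid
#' @param grid A `tile_grid`.
#' @return Integer tile count (`n_cols * n_rows`).
#' @export
n_tiles <- function(grid) grid$n_cols * grid$n_rows

#' Metric center of a grid tile
#' @param grid A `tile_grid`.
#' @param col,row 1-based tile indices.
#' @return Numeric length-2 vector `c(x_m, y_m)`.
#' @export
tile_center <- function(grid, col, row) {
  c(grid$origin_xy[1] + (col - 0.5) * grid$tile_size_m,
    grid$origin_xy[2] + (row - 0.5) * grid$tile_size_m)
}

#' Centers of all tiles in a grid
#' @param grid A `tile_grid`.
#' @return Tibble with `tile_id`, `col`, `row`, `x_m`, `y_m` in row-major
#'   (row, then column) order.
#' @export
tile_centers <- function(grid) {
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  tibble::tibble(
    tile_id = sprintf("r%04d_c%04d", row, col),
    col = col, row = row,
    x_m = grid$origin_xy[1] + (col - 0.5) * grid$tile_size_m,
    y_m = grid$origin_xy[2] + (row - 0.5) * grid$tile_size_m
  )
}

new_image_tile <- function(pixels, center_xy, source_resolution,
                           effective_resolution = source_resolution,
                           padded = FALSE) {
  structure(
    list(pixels = pixels, center_xy = as.numeric(center_xy),
         source_resolution = source_resolution,
         effective_resolution = effective_resolution,
         padded = isTRUE(padded)),
    class = "image_tile"
  )
}

#' @export
print.image_tile <- function(x, ...) {
  cat(sprintf("<image_tile> %d x %d px @ %g m/px (effective %g), center (%g, %g)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$source_resolution,
              x$effective_resolution, x$center_xy[1], x$center_xy[2],
              if (x$padded) ", zero-padded" else ""))
  invisible(x)
}

#' Extract one grid tile from a raster
#'
#' Tiles overhanging the raster boundary are zero-padded to the full tile
#' size and flagged `padded = TRUE` so region coverage is preserved.
#'
#' @param raster Numeric matrix (rows = y/southing, cols = x/easting) with
#'   values in `[0, 1]`, whose top-left pixel sits at the grid origin.
#' @param grid A `tile_grid` whose resolution matches the raster.
#' @param col,row 1-based tile indices.
#' @return An `image_tile`.
#' @export
extract_tile <- function(raster, grid, col, row) {
  if (col < 1 || col > grid$n_cols || row < 1 || row > grid$n_rows)
    stopf("tile index (col=%s, row=%s) outside grid %d x %d",
          col, row, grid$n_cols, grid$n_rows)
  size_px <- as.integer(round(grid$tile_size_m / grid$resolution_m_per_px))
  x0 <- (col - 1L) * size_px
  y0 <- (row - 1L) * size_px
  h <- nrow(raster); w <- ncol(raster)
  out <- matrix(0, size_px, size_px)
  ys <- (y0 + 1):min(y0 + size_px, h)
  xs <- (x0 + 1):min(x0 + size_px, w)
  padded <- length(ys) < size_px || length(xs) < size_px
  if (y0 < h && x0 < w)
    out[seq_along(ys), seq_along(xs)] <- raster[ys, xs]
  new_image_tile(out, tile_center(grid, col, row),
                 source_resolution = grid$resolution_m_per_px,
                 padded = padded)
}

#' Degrade the spatial resolution of a tile
#'
#' Implements the standard degradation protocol: the tile is scaled down so
#' its dimensions render the image at the coarser target resolution
#' (intermediate side length `round(H * source / target)`, half-up), then
#' upsampled back to the original pixel dimensions. This isolates the change
#' in spatial resolution while keeping all other image parameters fixed.
#' Downsampling is area-averaged (sensor footprint model), upsampling
#' bilinear.
#'
#' @param tile An `image_tile`.
#' @param target_resolution Target ground resolution in m/pixel; must be
#'   greater than or equal to the tile's source resolution (detail is never
#'   fabricated).
#' @return An `image_tile` of identical pixel dimensions with
#'   `effective_resolution` set to `target_resolution`.
#' @export
degrade_resolution <- function(tile, target_resolution) {
  src <- tile$source_resolution
  check_number(target_resolution, "target_resolution", positive = TRUE)
  if (target_resolution < src)
    stopf("target resolution (%g m/px) is finer than source (%g m/px); cannot fabricate detail",
          target_resolution, src)
  out <- tile
  out$effective_resolution <- target_resolution
  if (target_resolution == src) return(out)
  h <- nrow(tile$pixels); w <- ncol(tile$pixels)
  ih <- max(1L, as.integer(round_half_up(h * src / target_resolution)))
  iw <- max(1L, as.integer(round_half_up(w * src / target_resolution)))
  small <- resize_image(tile$pixels, ih, iw, method = "area")
  out$pixels <- resize_image(small, h, w, method = "bilinear")
  out
}

# ---- raster and grid I/O ---------------------------------------------------

#' Write a raster as TIFF with an ESRI world file
#'
#' Georeferencing is carried in a world-file sidecar (`.tfw`) holding the
#' affine transform; the scene convention (planar meters, y southward) maps
#' directly onto the image row order.
#'
#' @param raster Numeric matrix with values in `[0, 1]`.
#' @param path Output path ending in `.tif` or `.tiff`.
#' @param origin_xy Metric coordinates of the raster's top-left corner.
#' @param resolution_m_per_px Ground sampling distance.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(raster, path, origin_xy = c(0, 0),
                              resolution_m_per_px = 0.5) {
  tiff::writeTIFF(clamp(raster, 0, 1), path, bits.per.sample = 8L)
  wf <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  lines <- c(resolution_m_per_px, 0, 0, resolution_m_per_px,
             origin_xy[1] + resolution_m_per_px / 2,
             origin_xy[2] + resolution_m_per_px / 2)
  writeLines(format(lines, scientific = FALSE, trim = TRUE), wf)
  invisible(path)
}

#' Read a TIFF raster and its world file
#' @param path Path to a `.tif` written by [write_raster_tiff()].
#' @return List with `raster` (matrix), `origin_xy`, `resolution_m_per_px`.
#' @export
read_raster_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  wf <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  if (file.exists(wf)) {
    v <- as.numeric(readLines(wf))
    res <- v[1]
    origin <- c(v[5] - res / 2, v[6] - res / 2)
  } else {
    res <- NA_real_
    origin <- c(0, 0)
  }
  list(raster = img, origin_xy = origin, resolution_m_per_px = res)
}

#' Serialize a tile grid to JSON
#' @param grid A `tile_grid`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(origin_xy = grid$origin_xy, tile_size_m = grid$tile_size_m,
         n_cols = grid$n_cols, n_rows = grid$n_rows,
         resolution_m_per_px = grid$resolution_m_per_px,
         region_width_m = grid$region_width_m,
         region_height_m = grid$region_height_m,
         crs = "local-planar-meters"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tile grid from JSON
#' @param path JSON path written by [write_grid_json()].
#' @return A `tile_grid`.
#' @export
read_grid_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(origin_xy = as.numeric(j$origin_xy), tile_size_m = j$tile_size_m,
         n_cols = as.integer(j$n_cols), n_rows = as.integer(j$n_rows),
         resolution_m_per_px = j$resolution_m_per_px,
         region_width_m = j$region_width_m,
         region_height_m = j$region_height_m),
    class = "tile_grid")
}
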