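# Tile extraction from slide rasters: sliding-window grid enumeration,
# blank/non-tissue filtering by a color-saturation heuristic, and
# per-tile ROI coverage.
#
# Conventions: pixel coordinates are 0-based; a tile's window is the
# half-open rectangle [x0, x0+T) x [y0, y0+T), so windows at stride = T
# partition the cropped raster exactly and intersection areas carry no
# off-by-one error.  Partial edge tiles are dropped, never padded: the
# patch classifier requires a fixed input size.

#' Enumerate the sliding-window tile grid of a raster
#'
#' @param width,height Raster extent in pixels.
#' @param tile_size Tile side T in pixels (default 512).
#' @param stride Window step (default = `tile_size`, non-overlapping).
#' @param slide_id Slide identifier recorded on each tile.
#' @return Data frame of tile records: `slide_id`, 0-based grid indices
#'   `row`/`col`, top-left pixel `x0`/`y0` (x = column axis), and
#'   `tile_size`.  Exactly
#'   `floor((width - T)/stride + 1) * floor((height - T)/stride + 1)`
#'   rows (zero when the raster is smaller than one tile).
#' @export
tile_grid <- function(width, height, tile_size = 512L,
                      stride = tile_size, slide_id = "slide") {
  if (width < 1 || height < 1) stop_input("raster dimensions must be positive")
  if (tile_size < 1 || stride < 1) stop_input("tile_size and stride must be >= 1")
  n_cols <- floor((width - tile_size) / stride) + 1
  n_rows <- floor((height - tile_size) / stride) + 1
  if (n_cols < 1 || n_rows < 1) {
    return(data.frame(slide_id = character(0), row = integer(0),
                      col = integer(0), x0 = integer(0), y0 = integer(0),
                      tile_size = integer(0)))
  }
  grid <- expand.grid(col = seq_len(n_cols) - 1L,
                      row = seq_len(n_rows) - 1L)
  data.frame(slide_id = slide_id, row = grid$row, col = grid$col,
             x0 = grid$col * as.integer(stride),
             y0 = grid$row * as.integer(stride),
             tile_size = as.integer(tile_size))
}

#' Tissue/blank decision for one tile by color thresholds
#'
#' A pixel counts as tissue when its HSV saturation exceeds
#' `saturation_thresh` and its value (brightness) is below
#' `white_cutoff`; the tile is tissue when the tissue-pixel fraction
#' reaches `tissue_frac_thresh`.  This is the standard color-threshold
#' stand-in for a trained tissue/non-tissue classifier; a fitted model
#' can be plugged in via the `classifier` hook, which receives the tile
#' array and overrides the heuristic.
#'
#' @param tile_pixels H x W x 3 numeric array in \[0,1\] (or 0..255,
#'   rescaled internally).
#' @param saturation_thresh Minimum saturation for a tissue pixel
#'   (default 0.07).
#' @param tissue_frac_thresh Minimum tissue-pixel fraction (default 0.25).
#' @param white_cutoff Value ceiling excluding near-white glass
#'   (default 0.95).
#' @param classifier Optional function(tile_pixels) -> logical.
#' @return Logical: is the tile tissue?
#' @export
blank_filter <- function(tile_pixels, saturation_thresh = 0.07,
                         tissue_frac_thresh = 0.25,
                         white_cutoff = 0.95, classifier = NULL) {
  if (!is.null(classifier)) return(isTRUE(classifier(tile_pixels)))
  if (length(tile_pixels) == 0L) stop_input("empty tile")
  d <- dim(tile_pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop_input("tile must be an H x W x 3 RGB array")
  }
  if (max(tile_pixels) > 1) tile_pixels <- tile_pixels / 255
  rgb <- matrix(tile_pixels, ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 1)
  tissue_frac <- mean(hsv["s", ] > saturation_thresh &
                      hsv["v", ] < white_cutoff)
  tissue_frac >= tissue_frac_thresh
}

# --- ROI coverage -----------------------------------------------------

#' Fraction of a tile window covered by a rasterized ROI mask
#'
#' @param x0,y0 Tile top-left pixel (0-based; x indexes columns).
#' @param tile_size Tile side.
#' @param mask Binary matrix, rows = y (height), cols = x (width), in
#'   the same pixel frame as the tile.
#' @return Covered-area fraction in \[0,1\].
#' @export
roi_fraction_mask <- function(x0, y0, tile_size, mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (x0 < 0 || y0 < 0 || x0 + tile_size > w || y0 + tile_size > h) {
    stop_input("tile window exceeds the ROI mask extent ",
               "(coordinate-frame mismatch?)")
  }
  sub <- mask[(y0 + 1L):(y0 + tile_size), (x0 + 1L):(x0 + tile_size)]
  mean(sub != 0)
}

# Sutherland-Hodgman clip of a simple polygon against an axis-aligned
# half-plane; vertices as a 2-column matrix (x, y).
clip_halfplane <- function(poly, axis, bound, keep_leq) {
  if (!nrow(poly)) return(poly)
  inside <- if (keep_leq) poly[, axis] <= bound else poly[, axis] >= bound
  out <- matrix(numeric(0), ncol = 2L)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (inside[i]) out <- rbind(out, p)
    if (inside[i] != inside[j]) {
      t <- (bound - p[axis]) / (q[axis] - p[axis])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Fraction of a tile window covered by polygonal ROI geometry
#'
#' Clips each polygon to the tile rectangle (Sutherland-Hodgman, exact
#' for simple polygons against a convex window) and sums shoelace
#' areas.  Overlapping polygons are not deduplicated; annotation
#' exports are assumed disjoint.
#'
#' @param x0,y0,tile_size Tile window as in [roi_fraction_mask()].
#' @param polygons List of 2-column (x, y) vertex matrices in pixel
#'   coordinates.
#' @param raster_extent Optional `c(width, height)`; when given,
#'   polygons reaching outside it raise a coordinate-frame error.
#' @return Covered-area fraction in \[0,1\].
#' @export
roi_fraction_polygon <- function(x0, y0, tile_size, polygons,
                                 raster_extent = NULL) {
  if (!is.null(raster_extent)) {
    for (poly in polygons) {
      if (any(poly[, 1L] < 0 | poly[, 1L] > raster_extent[1] |
              poly[, 2L] < 0 | poly[, 2L] > raster_extent[2])) {
        stop_input("ROI polygon exceeds the raster extent ",
                   "(coordinate-frame mismatch?)")
      }
    }
  }
  area <- 0
  for (poly in polygons) {
    clipped <- clip_halfplane(poly, 1L, x0, keep_leq = FALSE)
    clipped <- clip_halfplane(clipped, 1L, x0 + tile_size, keep_leq = TRUE)
    clipped <- clip_halfplane(clipped, 2L, y0, keep_leq = FALSE)
    clipped <- clip_halfplane(clipped, 2L, y0 + tile_size, keep_leq = TRUE)
    area <- area + shoelace_area(clipped)
  }
  min(area / tile_size^2, 1)
}

#' Read ROI polygons from a GeoJSON annotation export
#'
#' Accepts FeatureCollection / Feature / bare-geometry GeoJSON holding
#' Polygon or MultiPolygon geometries (the format QuPath-style
#' annotation tools export); interior rings are ignored.
#'
#' @param path Path to a GeoJSON file.
#' @return List of 2-column (x, y) vertex matrices.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geoms <- switch(gj$type %||% "",
    FeatureCollection = lapply(gj$features, `[[`, "geometry"),
    Feature = list(gj$geometry),
    Polygon = , MultiPolygon = list(gj),
    stop_input("unsupported GeoJSON type: ", gj$type %||% "<missing>"))
  polys <- list()
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
  }
  for (g in geoms) {
    if (is.null(g)) next
    if (g$type == "Polygon") {
      polys <- c(polys, list(ring_to_matrix(g$coordinates[[1]])))
    } else if (g$type == "MultiPolygon") {
      for (p in g$coordinates) {
        polys <- c(polys, list(ring_to_matrix(p[[1]])))
      }
    }
  }
  polys
}

#' Tile a slide raster into records with tissue flags and ROI coverage
#'
#' The full tiling stage: grid enumeration, blank filtering on the
#' pixel content of each window, and ROI-coverage bookkeeping against a
#' mask or polygon set.
#'
#' @param raster H x W x 3 array in \[0,1\].
#' @param roi Either `NULL`, a binary H x W mask matrix, or a list of
#'   polygon vertex matrices.
#' @param tile_size,stride Grid geometry.
#' @param slide_id Identifier stamped on records.
#' @param ... Passed to [blank_filter()].
#' @return Data frame extending [tile_grid()] with `tissue` (logical)
#'   and `roi_fraction`.
#' @export
tile_slide <- function(raster, roi = NULL, tile_size = 512L,
                       stride = tile_size, slide_id = "slide", ...) {
  d <- dim(raster)
  if (length(d) != 3L || d[3] != 3L) stop_input("raster must be H x W x 3")
  tiles <- tile_grid(width = d[2], height = d[1], tile_size = tile_size,
                     stride = stride, slide_id = slide_id)
  n <- nrow(tiles)
  tiles$tissue <- logical(n)
  tiles$roi_fraction <- numeric(n)
  for (i in seq_len(n)) {
    rows <- (tiles$y0[i] + 1L):(tiles$y0[i] + tile_size)
    cols <- (tiles$x0[i] + 1L):(tiles$x0[i] + tile_size)
    tiles$tissue[i] <- blank_filter(raster[rows, cols, , drop = FALSE], ...)
    tiles$roi_fraction[i] <- if (is.null(roi)) {
      0
    } else if (is.matrix(roi)) {
      roi_fraction_mask(tiles$x0[i], tiles$y0[i], tile_size, roi)
    } else {
      roi_fraction_polygon(tiles$x0[i], tiles$y0[i], tile_size, roi,
                           raster_extent = c(d[2], d[1]))
    }
  }
  tiles
}

#' Extract the pixel window of one tile record
#'
#' @param raster H x W x 3 array.
#' @param tile One row of a tile-record data frame.
#' @return `tile_size` x `tile_size` x 3 array.
#' @export
tile_pixels <- function(raster, tile) {
  ts <- tile$tile_size
  raster[(tile$y0 + 1L):(tile$y0 + ts),
         (tile$x0 + 1L):(tile$x0 + ts), , drop = FALSE]
}
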