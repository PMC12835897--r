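test_that("tile_grid enumerates exactly the full windows", {
  expect_equal(nrow(tile_grid(1024, 1024, 512)), 4)
  expect_equal(nrow(tile_grid(511, 511, 512)), 0)
  g <- tile_grid(1536, 1024, 512, stride = 256)
  expect_equal(nrow(g), 15)
  # brute-force enumeration oracle over a parameter grid
  for (w in c(512, 700, 1300)) {
    for (s in c(128, 512)) {
      got <- nrow(tile_grid(w, 1024, 512, stride = s))
      want <- sum(vapply(seq(0, w, by = s),
                         function(x0) x0 + 512 <= w, logical(1))) *
              sum(vapply(seq(0, 1024, by = s),
                         function(y0) y0 + 512 <= 1024, logical(1)))
      expect_equal(got, want)
    }
  }
  expect_error(tile_grid(0, 100), "positive")
})

test_that("stride = tile_size windows partition the cropped raster", {
  g <- tile_grid(1100, 700, 256)
  # each retained pixel is covered exactly once
  cover <- matrix(0L, 700, 1100)
  for (i in seq_len(nrow(g))) {
    rows <- (g$y0[i] + 1):(g$y0[i] + 256)
    cols <- (g$x0[i] + 1):(g$x0[i] + 256)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover[1:512, 1:1024] == 1L))
  expect_true(all(cover[513:700, ] == 0L) && all(cover[, 1025:1100] == 0L))
})

test_that("blank filter separates glass from tissue by saturation", {
  white <- solid_tile(c(1, 1, 1))
  pink <- solid_tile(c(0.85, 0.55, 0.7))
  expect_false(blank_filter(white))
  expect_true(blank_filter(pink))
  half <- white
  half[, 1:4, ] <- pink[, 1:4, ]
  expect_true(blank_filter(half, tissue_frac_thresh = 0.4))
  expect_false(blank_filter(half, tissue_frac_thresh = 0.6))
  expect_error(blank_filter(array(0, c(0, 0, 3))), "empty")
  # pluggable classifier hook overrides the heuristic
  expect_true(blank_filter(white, classifier = function(t) TRUE))
})

test_that("mask-based ROI coverage is exact rectangle arithmetic", {
  mask_full <- matrix(1L, 64, 64)
  mask_none <- matrix(0L, 64, 64)
  expect_equal(roi_fraction_mask(0, 0, 32, mask_full), 1.0)
  expect_equal(roi_fraction_mask(32, 32, 32, mask_none), 0.0)
  quad <- matrix(0L, 64, 64)
  quad[1:16, 1:16] <- 1L  # one quadrant of the (0,0) 32-tile
  expect_equal(roi_fraction_mask(0, 0, 32, quad), 0.25)
  expect_error(roi_fraction_mask(40, 0, 32, quad), "mismatch")
})

test_that("polygon ROI coverage matches exact areas and the mask path", {
  sq <- cbind(c(0, 16, 16, 0), c(0, 0, 16, 16))
  expect_equal(roi_fraction_polygon(0, 0, 32, list(sq)), 0.25)
  # triangle covering half the tile
  tri <- cbind(c(0, 32, 0), c(0, 0, 32))
  expect_equal(roi_fraction_polygon(0, 0, 32, list(tri)), 0.5)
  # rasterized-mask agreement within the 1/T-per-side bound
  poly <- cbind(c(5, 27, 27, 5), c(3, 3, 29, 29))
  mask <- matrix(0L, 32, 32)
  mask[4:29, 6:27] <- 1L  # pixel-center rasterization of the rectangle
  f_poly <- roi_fraction_polygon(0, 0, 32, list(poly))
  f_mask <- roi_fraction_mask(0, 0, 32, mask)
  expect_lt(abs(f_poly - f_mask), 4 / 32)
  expect_error(
    roi_fraction_polygon(0, 0, 32, list(sq), raster_extent = c(8, 8)),
    "mismatch")
})

test_that("growing the ROI never decreases any tile's coverage", {
  set.seed(13)
  mask_small <- matrix(0L, 96, 96)
  mask_small[20:50, 30:60] <- 1L
  mask_big <- mask_small
  mask_big[10:70, 15:80] <- 1L
  g <- tile_grid(96, 96, 32)
  for (i in seq_len(nrow(g))) {
    expect_gte(roi_fraction_mask(g$x0[i], g$y0[i], 32, mask_big),
               roi_fraction_mask(g$x0[i], g$y0[i], 32, mask_small))
  }
})

test_that("GeoJSON polygons round-trip into coverage fractions", {
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(list(list(0, 0), list(16, 0),
                                              list(16, 16), list(0, 16),
                                              list(0, 0)))))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  polys <- read_roi_geojson(path)
  expect_length(polys, 1)
  expect_equal(roi_fraction_polygon(0, 0, 32, polys), 0.25)
})

test_that("tile_slide combines grid, tissue flags and ROI coverage", {
  cfg <- slide_sim_config(3, 3, tile_size = 16, malignant_fraction = 0.5,
                          blank_fraction = 0.3, seed = 5)
  sl <- simulate_slide(cfg)
  td <- tile_slide(sl$raster, roi = sl$roi_mask, tile_size = 16,
                   slide_id = "sim")
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$tissue), sum(!sl$tiles$blank))
  # planted region aligns with tiles: coverage is exactly 0 or 1
  expect_true(all(td$roi_fraction %in% c(0, 1)))
  expect_equal(sum(td$roi_fraction == 1), sum(sl$tiles$in_roi))
})
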