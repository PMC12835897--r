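test_that("the supervised coverage rule follows the strict over-threshold reading", {
  expect_equal(supervised_label(0.85), 1L)
  expect_equal(supervised_label(0.0), 0L)
  expect_equal(supervised_label(0.80), -1L)  # exactly at theta: discarded
  expect_equal(supervised_label(c(1, 0.5, 0)), c(1L, -1L, 0L))
  expect_error(supervised_label(1.2), "\\[0, 1\\]")
})

test_that("weak labels propagate the slide label to every patch", {
  expect_equal(weak_label(0L, 5), rep(0L, 5))
  expect_equal(weak_label(1L, 100), rep(1L, 100))
  expect_length(weak_label(1L, 0), 0)
  expect_error(weak_label(NA, 3), "0 or 1")
})

make_tiles_df <- function(roi_fracs, tissue = TRUE) {
  data.frame(slide_id = "s", row = seq_along(roi_fracs) - 1L, col = 0L,
             x0 = 0L, y0 = 0L, tile_size = 32L,
             tissue = rep_len(tissue, length(roi_fracs)),
             roi_fraction = roi_fracs)
}

test_that("patch-set selection matches each strategy's contract", {
  # 10 tissue tiles, 4 with ROI overlap
  tiles <- make_tiles_df(c(rep(0, 6), 0.3, 0.9, 1, 0.85))
  conv <- select_patch_set(tiles, labeling_policy("conventional"),
                           slide_label = 1L)
  expect_equal(nrow(conv), 4)
  ext <- select_patch_set(tiles, labeling_policy("extended"),
                          slide_label = 1L)
  expect_equal(nrow(ext), 10)
  weak <- select_patch_set(tiles, labeling_policy("weak"),
                           slide_label = 1L)
  expect_equal(ext, weak)  # definitional identity

  sup <- select_patch_set(make_tiles_df(c(1.0, 0.5, 0.0)),
                          labeling_policy("supervised"))
  expect_equal(nrow(sup), 2)
  expect_setequal(sup$label, c(1L, 0L))
})

test_that("supervised labeling partitions tissue tiles across {1, 0, discard}", {
  set.seed(17)
  fr <- round(runif(50), 2)
  lab <- supervised_label(fr)
  expect_true(all(lab %in% c(1L, 0L, -1L)))
  expect_equal(sum(lab == 1) + sum(lab == 0) + sum(lab == -1), 50)
  tiles <- make_tiles_df(fr)
  kept <- select_patch_set(tiles, labeling_policy("supervised"))
  expect_equal(nrow(kept), sum(lab != -1L))
  # conventional never exceeds extended
  conv <- select_patch_set(tiles, labeling_policy("conventional"),
                           slide_label = 1L)
  ext <- select_patch_set(tiles, labeling_policy("extended"),
                          slide_label = 1L)
  expect_lte(nrow(conv), nrow(ext))
})

test_that("non-tissue tiles never enter a patch set", {
  tiles <- make_tiles_df(rep(0.9, 6), tissue = c(TRUE, FALSE))
  sel <- select_patch_set(tiles, labeling_policy("extended"),
                          slide_label = 1L)
  expect_equal(nrow(sel), 3)
})

test_that("conventional selection warns when a slide has no ROI", {
  tiles <- make_tiles_df(rep(0, 4))
  expect_warning(
    sel <- select_patch_set(tiles, labeling_policy("conventional"),
                            slide_label = 0L),
    "no ROI")
  expect_equal(nrow(sel), 0)
})

test_that("mutation/LNM endpoints inherit the slide's endpoint label", {
  tiles <- make_tiles_df(c(0, 0.9, 1))
  pol <- labeling_policy("extended", endpoint = "braf")
  sel <- select_patch_set(tiles, pol, slide_label = 0L)
  expect_true(all(sel$label == 0L))
})

test_that("weak patch-label error on malignant slides equals one minus rho", {
  cohort <- simulate_slide_cohort(6, grid_rows = 6, grid_cols = 6,
                                  tile_size = 16,
                                  rho_range = c(0.2, 0.6),
                                  blank_fraction = 0.2, seed = 23)
  for (i in seq_along(cohort$slides)) {
    s <- cohort$slides[[i]]
    if (cohort$labels[i] == 0L) next
    truth <- s$tiles[!s$tiles$blank, ]
    weak <- weak_label(1L, nrow(truth))
    err <- mean(weak != as.integer(truth$in_roi))
    expect_equal(err, 1 - s$rho)
  }
})
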