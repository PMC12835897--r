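# End-to-end slide classification from a corpus of patch-likelihood
# bags: PLH + TF-IDF aggregation, z-normalization, correlation
# filtering, cross-validated LASSO selection, slide classifiers, and
# evaluation on a stratified held-out split.

#' Run the patch-to-slide pipeline on a likelihood corpus
#'
#' The full WSI-level workflow downstream of the patch classifier:
#' slide features by fused PLH + TF-IDF aggregation (idf fit on the
#' training slides), feature scaling / Pearson filtering / LASSO
#' selection fit on the training split only, the requested slide
#' classifiers tuned by inner CV, and an [eval_report()] per family on
#' the held-out split.  Also reports the patch-level AUC of the raw
#' likelihoods against slide labels, the baseline the aggregation is
#' meant to improve on.
#'
#' @param bags List of [likelihood_bag()].
#' @param labels Named binary slide labels aligned with `bags`.
#' @param ratio Training fraction for the stratified split (default
#'   0.7).
#' @param n_bins Likelihood bins for PLH/BoW (default 10).
#' @param families Slide classifier families (default all three).
#' @param r_thresh,k_folds Selection-stage settings.
#' @param seed Integer seed driving split, folds and model fits.
#' @return List with `split`, `selection`, `models`, `scores` (test
#'   slides x families), `reports` (per family), `best` (family with
#'   highest test AUC), `patch_auc`, and `slide_auc` (best family).
#' @export
run_slide_pipeline <- function(bags, labels, ratio = 0.7, n_bins = 10L,
                               families = c("lr", "svm", "rf"),
                               r_thresh = 0.9, k_folds = 10L,
                               seed = 1L) {
  if (length(bags) != length(labels)) {
    stop_input("bags/labels length mismatch")
  }
  ids <- names(labels) %||% vapply(bags, `[[`, character(1), "slide_id")
  names(labels) <- ids
  split <- stratified_split(ids, labels, ratio = ratio, seed = seed)
  tr <- match(split$train_ids, ids)
  te <- match(split$test_ids, ids)

  agg <- aggregate_corpus(bags, n_bins = n_bins, train_idx = tr)
  sel <- select_features(agg$features[tr, , drop = FALSE],
                         agg$features[te, , drop = FALSE],
                         labels[tr], r_thresh = r_thresh,
                         k_folds = k_folds, seed = seed)
  models <- fit_slide_models(sel$train, labels[tr],
                             families = families, seed = seed)
  scores <- predict_slide_models(models, sel$test)
  reports <- lapply(seq_len(ncol(scores)), function(j) {
    eval_report(scores[, j], labels[te])
  })
  names(reports) <- colnames(scores)
  aucs <- vapply(reports, `[[`, numeric(1), "auc")
  best <- names(which.max(aucs))

  # patch-level baseline: every patch scored against its slide's label
  patch_scores <- unlist(lapply(bags[te], `[[`, "p_malignant"))
  patch_labels <- rep(labels[te], vapply(bags[te], length, integer(1)))
  patch_auc <- roc_auc(patch_scores, patch_labels)$auc

  list(split = split, selection = sel, models = models,
       scores = scores, reports = reports, best = best,
       slide_auc = unname(aucs[best]), patch_auc = patch_auc)
}

# --- light-weight I/O -------------------------------------------------

#' Write / read a slide-level label manifest
#'
#' The manifest is the pipeline's bookkeeping table: one row per slide
#' with its malignancy, mutation and lymph-node-metastasis labels.
#'
#' @param manifest Data frame with at least `slide_id` and one label
#'   column.
#' @param path CSV path.
#' @return The manifest (invisibly for the writer).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a slide raster or binary mask as PNG
#'
#' @param x H x W x 3 array in \[0,1\] (raster) or H x W 0/1 matrix
#'   (mask).
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(x, path) {
  png::writePNG(x, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @export
read_slide_png <- function(path) {
  png::readPNG(path)
}

#' Generate a cohort of synthetic tiled slides
#'
#' Draws `n_slides` slides (alternating benign/malignant by
#' `class_prior` rounding), each malignant slide planting a contiguous
#' lesion covering rho ~ Uniform(`rho_range`) of its tissue tiles.
#'
#' @param n_slides Cohort size.
#' @param grid_rows,grid_cols,tile_size,blank_fraction Per-slide
#'   geometry (see [slide_sim_config()]).
#' @param rho_range Lesion fraction interval for malignant slides.
#' @param class_prior Malignant fraction of the cohort.
#' @param seed Integer seed.
#' @return List with `slides` (each a [simulate_slide()] result plus
#'   `slide_id` and realized `rho`) and `labels` (named 0/1 vector).
#' @export
simulate_slide_cohort <- function(n_slides, grid_rows = 5L,
                                  grid_cols = 5L, tile_size = 32L,
                                  rho_range = c(0.3, 0.6),
                                  blank_fraction = 0.1,
                                  class_prior = 0.5, seed = 1L) {
  n_pos <- round(class_prior * n_slides)
  labels <- with_seed(child_seed(seed, 0L),
                      sample(rep(c(1L, 0L), c(n_pos, n_slides - n_pos))))
  names(labels) <- sprintf("slide_%03d", seq_len(n_slides))
  slides <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    rho <- if (labels[i] == 1L) {
      with_seed(child_seed(seed, i), stats::runif(1, rho_range[1],
                                                  rho_range[2]))
    } else 0
    cfg <- slide_sim_config(grid_rows, grid_cols, tile_size = tile_size,
                            malignant_fraction = rho,
                            blank_fraction = blank_fraction,
                            seed = child_seed(seed, 10000L + i))
    s <- simulate_slide(cfg)
    s$slide_id <- names(labels)[i]
    s$rho <- if (labels[i] == 1L) {
      sum(s$tiles$in_roi) / sum(!s$tiles$blank)
    } else 0
    slides[[i]] <- s
  }
  list(slides = slides, labels = labels)
}

#' Patch-to-slide experiment on synthetic tiled slides
#'
#' Runs the imaging half of the pipeline end to end: tiles every slide,
#' labels training patches under the given policy, trains the patch
#' classifier, scores all tissue tiles of the held-out slides, and
#' aggregates each test slide's likelihood bag into a slide score
#' (mean patch likelihood).  For the weak policy it also reports the
#' patch-label error rate on malignant training slides, which equals
#' 1 - rho by construction.
#'
#' @param train_cohort,test_cohort Cohorts from
#'   [simulate_slide_cohort()] (built with the same tile size).
#' @param policy A [labeling_policy()].
#' @param tile_size Tile side used at generation time.
#' @param cfg A [train_config()] for the patch classifier.
#' @return List with `slide_auc`, `patch_model`, `slide_scores`,
#'   `slide_labels`, `weak_label_error` (NA unless the policy ignores
#'   ROIs) and `mean_rho_malignant`.
#' @export
run_tiled_slide_experiment <- function(train_cohort, test_cohort,
                                       policy = labeling_policy("weak"),
                                       tile_size = 32L,
                                       cfg = train_config()) {
  tiles_px <- list()
  labs <- integer(0)
  err_num <- 0; err_den <- 0
  for (s in train_cohort$slides) {
    td <- tile_slide(s$raster, roi = s$roi_mask, tile_size = tile_size,
                     slide_id = s$slide_id)
    lab <- train_cohort$labels[[s$slide_id]]
    sel <- select_patch_set(td, policy, slide_label = lab)
    if (!nrow(sel)) next
    px <- lapply(seq_len(nrow(sel)), function(j) {
      tile_pixels(s$raster, sel[j, ])
    })
    tiles_px <- c(tiles_px, px)
    labs <- c(labs, sel$label)
    if (policy$strategy %in% c("weak", "extended") && lab == 1L) {
      truth <- sel$roi_fraction > 0.5  # planted lesions align with tiles
      err_num <- err_num + sum(sel$label != truth)
      err_den <- err_den + nrow(sel)
    }
  }
  model <- train_patch_classifier(tiles_px, labs, cfg)
  scores <- numeric(length(test_cohort$slides))
  for (i in seq_along(test_cohort$slides)) {
    s <- test_cohort$slides[[i]]
    td <- tile_slide(s$raster, tile_size = tile_size,
                     slide_id = s$slide_id)
    bag <- score_slide(model, s$raster, td)
    scores[i] <- mean(bag$p_malignant)
  }
  labels <- as.integer(test_cohort$labels)
  rhos <- vapply(train_cohort$slides, `[[`, numeric(1), "rho")
  list(slide_auc = roc_auc(scores, labels)$auc,
       patch_model = model, slide_scores = scores,
       slide_labels = labels,
       weak_label_error = if (err_den > 0) err_num / err_den else NA_real_,
       mean_rho_malignant = mean(rhos[rhos > 0]))
}
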