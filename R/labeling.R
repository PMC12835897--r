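# Patch labeling strategies.  Four policies cover the two axes the
# pipeline explores: whether ROI annotations are used (supervised /
# conventional) or only the slide label (weak / extended), and whether
# training patches come from the ROI only (conventional) or the whole
# slide (extended).

LABEL_DISCARD <- -1L

#' Labeling policy for patch selection and label assignment
#'
#' @param strategy One of `"supervised"` (ROI-coverage rule with
#'   discards), `"weak"` (slide label propagated to every tissue
#'   patch), `"conventional"` (ROI patches only), `"extended"` (all
#'   tissue patches, slide label).
#' @param roi_threshold Coverage threshold theta for the supervised
#'   rule (default 0.8: a patch is malignant only when *over* 80% of it
#'   lies in the ROI).
#' @param roi_min_fraction Minimum ROI overlap for inclusion under the
#'   conventional strategy (default: any positive overlap).
#' @param endpoint Which slide endpoint the labels encode
#'   (`"malignancy"`, `"braf"`, `"lnm"`).  For mutation and
#'   lymph-node-metastasis endpoints patch labels always inherit the
#'   slide's endpoint label.
#' @return Object of class `labeling_policy`.
#' @export
labeling_policy <- function(strategy = c("supervised", "weak",
                                         "conventional", "extended"),
                            roi_threshold = 0.8,
                            roi_min_fraction = 0,
                            endpoint = c("malignancy", "braf", "lnm")) {
  strategy <- match.arg(strategy)
  endpoint <- match.arg(endpoint)
  if (!(roi_threshold > 0 && roi_threshold <= 1)) {
    stop_config("roi_threshold must lie in (0, 1]")
  }
  structure(list(strategy = strategy, roi_threshold = roi_threshold,
                 roi_min_fraction = roi_min_fraction,
                 endpoint = endpoint),
            class = "labeling_policy")
}

#' Supervised patch label from ROI coverage
#'
#' The coverage rule: a patch covered more than `theta` by the ROI is
#' malignant (1); a patch with no ROI overlap is benign (0); patches
#' with intermediate coverage are discarded from training (returned as
#' -1).  "Over" is read strictly, so coverage exactly at `theta` is
#' discarded.
#'
#' @param roi_fraction Coverage value(s) in \[0,1\] (vectorized).
#' @param theta Threshold (default 0.8).
#' @return Integer vector: 1, 0 or -1 (discard).
#' @export
supervised_label <- function(roi_fraction, theta = 0.8) {
  if (any(!is.finite(roi_fraction)) ||
      any(roi_fraction < 0 | roi_fraction > 1)) {
    stop_input("roi_fraction must lie in [0, 1]")
  }
  ifelse(roi_fraction > theta, 1L,
         ifelse(roi_fraction == 0, 0L, LABEL_DISCARD))
}

#' Weak patch label from the slide label
#'
#' Every tissue patch of the slide inherits the slide-level label; no
#' ROI information is consulted.  This is the label-noise-bearing
#' strategy: on a malignant slide whose lesion covers a fraction rho of
#' the tissue, a fraction 1 - rho of patches are mislabeled by
#' construction.
#'
#' @param slide_label 0 or 1.
#' @param n_patches Number of tissue patches on the slide.
#' @return Integer vector of length `n_patches`.
#' @export
weak_label <- function(slide_label, n_patches) {
  if (length(slide_label) != 1L || is.na(slide_label) ||
      !slide_label %in% c(0L, 1L)) {
    stop_input("slide_label must be 0 or 1")
  }
  rep(as.integer(slide_label), n_patches)
}

#' Select and label the training patch set under a policy
#'
#' @param tiles Tile-record data frame carrying `tissue` and
#'   `roi_fraction` columns (from [tile_slide()]).
#' @param policy A [labeling_policy()].
#' @param slide_label The slide's endpoint label (required by every
#'   strategy except supervised malignancy labeling).
#' @return The selected subset of `tiles` with a `label` column
#'   (supervised discards are removed from the returned set).
#' @export
select_patch_set <- function(tiles, policy, slide_label = NULL) {
  stopifnot(inherits(policy, "labeling_policy"))
  tissue <- tiles[tiles$tissue, , drop = FALSE]
  need_slide_label <- policy$strategy %in% c("weak", "extended") ||
    policy$endpoint != "malignancy"
  if (need_slide_label && is.null(slide_label)) {
    stop_input("this policy requires the slide-level label")
  }
  out <- switch(policy$strategy,
    supervised = {
      lab <- supervised_label(tissue$roi_fraction, policy$roi_threshold)
      keep <- tissue[lab != LABEL_DISCARD, , drop = FALSE]
      keep$label <- lab[lab != LABEL_DISCARD]
      keep
    },
    weak = ,
    extended = {
      tissue$label <- weak_label(slide_label, nrow(tissue))
      tissue
    },
    conventional = {
      keep <- tissue[tissue$roi_fraction > policy$roi_min_fraction, ,
                     drop = FALSE]
      if (!nrow(keep)) {
        warning("conventional strategy found no ROI patches on slide")
      }
      keep$label <- rep(as.integer(slide_label %||% 1L), nrow(keep))
      keep
    })
  # mutation / LNM endpoints train against the slide's endpoint label
  if (policy$endpoint != "malignancy") {
    out$label <- rep(as.integer(slide_label), nrow(out))
  }
  rownames(out) <- NULL
  out
}
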