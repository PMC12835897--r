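# Evaluation: empirical ROC curves, AUC, the confusion-matrix metric
# panel, and slide probability maps.

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC curve over all score thresholds and its area
#' by the trapezoidal rule.  With ties handled by grouping equal scores
#' into a single threshold, the trapezoidal area equals the Mann-Whitney
#' U statistic scaled to \eqn{[0,1]} (tied positive/negative pairs count
#' one half), i.e. the probability that a randomly chosen positive slide
#' outscores a randomly chosen negative one.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Binary vector (0/1 or logical) of true classes; both
#'   classes must be present.
#' @return A list with `auc` (scalar) and `roc`, a data frame of
#'   (`threshold`, `fpr`, `tpr`) points starting at (0,0) and ending at
#'   (1,1), monotone non-decreasing in both coordinates.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop_input("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) stop_input("NA in scores or labels")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_input("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores into one threshold step
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1L - y)[!duplicated(grp, fromLast = TRUE)]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thr <- c(Inf, s[!duplicated(grp, fromLast = TRUE)])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Confusion counts at a score threshold
#'
#' @param scores Numeric scores in any range.
#' @param labels Binary truth.
#' @param threshold Scores strictly above `threshold` are called positive
#'   (default 0.5, the convention for probability scores).
#' @return Named list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == 0L),
       tn = sum(pred == 0L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Accuracy, precision, sensitivity and F1 from confusion counts
#'
#' Ratios with a zero denominator are reported as 0 and flagged in the
#' `undefined` field rather than returned as NaN, so reports can be
#' aggregated robustly.
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn` (non-negative integers).
#' @return List with `accuracy`, `precision`, `sensitivity`, `f1`,
#'   `n`, and `undefined` (character vector naming flagged metrics).
#' @export
metric_panel <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  vals <- c(tp, fp, tn, fn)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_input("confusion counts must be non-negative")
  }
  n <- tp + fp + tn + fn
  if (n < 1) stop_input("empty confusion table")
  undefined <- character(0)
  safe_ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  sensitivity <- safe_ratio(tp, tp + fn, "sensitivity")
  f1 <- if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f1"); 0
  } else 2 * precision * sensitivity / (precision + sensitivity)
  list(accuracy = (tp + tn) / n, precision = precision,
       sensitivity = sensitivity, f1 = f1, n = n, undefined = undefined)
}

#' Full evaluation report for one classifier on one test split
#'
#' @inheritParams roc_auc
#' @param threshold Threshold for the confusion-based panel.
#' @return List of class `slidewise_eval`: confusion counts, ROC points,
#'   AUC, the metric panel, and `n_test`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  ra <- roc_auc(scores, labels)
  cc <- confusion_counts(scores, labels, threshold)
  mp <- metric_panel(cc)
  structure(list(counts = cc, auc = ra$auc, roc = ra$roc,
                 accuracy = mp$accuracy, precision = mp$precision,
                 sensitivity = mp$sensitivity, f1 = mp$f1,
                 undefined = mp$undefined, threshold = threshold,
                 n_test = mp$n),
            class = "slidewise_eval")
}

#' @export
print.slidewise_eval <- function(x, ...) {
  cat(sprintf("Slide-level evaluation (n = %d, threshold = %g)\n",
              x$n_test, x$threshold))
  cat(sprintf("  AUC %.3f | accuracy %.3f | precision %.3f | sensitivity %.3f | F1 %.3f\n",
              x$auc, x$accuracy, x$precision, x$sensitivity, x$f1))
  invisible(x)
}

#' Scatter per-tile probabilities onto a slide-shaped grid
#'
#' Builds the slide probability map used for localization figures: cell
#' (r, c) holds the tile's malignant-class probability, cells with no
#' scored tile hold `NA` (no tissue).
#'
#' @param bag A [likelihood_bag()].
#' @param grid_rows,grid_cols Grid extent in tiles.
#' @return `grid_rows` x `grid_cols` numeric matrix with `NA` for
#'   unscored cells.
#' @export
probability_map <- function(bag, grid_rows, grid_cols) {
  stopifnot(inherits(bag, "likelihood_bag"))
  if (grid_rows < 1 || grid_cols < 1) stop_input("grid must be positive")
  if (any(bag$row < 0) || any(bag$row >= grid_rows) ||
      any(bag$col < 0) || any(bag$col >= grid_cols)) {
    stop_input("tile coordinate outside the stated grid")
  }
  idx <- bag$row * grid_cols + bag$col
  if (anyDuplicated(idx)) stop_input("duplicate tile coordinate in bag")
  m <- matrix(NA_real_, nrow = grid_rows, ncol = grid_cols)
  m[cbind(bag$row + 1L, bag$col + 1L)] <- bag$p_malignant
  m
}
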