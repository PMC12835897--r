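# Core containers passed between pipeline stages.

#' Per-slide bag of patch likelihoods
#'
#' The unit of exchange between the patch classifier and the slide-level
#' aggregation stages: one malignant-class probability per scored tile,
#' together with the tile's grid coordinates.
#'
#' @param slide_id Character scalar.
#' @param p_malignant Numeric vector in \eqn{[0,1]}, one entry per tile.
#' @param row,col Integer 0-based grid coordinates, same length as
#'   `p_malignant` (defaults lay tiles on a single row).
#' @return Object of class `likelihood_bag`.
#' @export
likelihood_bag <- function(slide_id, p_malignant,
                           row = integer(length(p_malignant)),
                           col = seq_along(p_malignant) - 1L) {
  p_malignant <- as.numeric(p_malignant)
  if (length(p_malignant) &&
      (anyNA(p_malignant) || any(p_malignant < 0 | p_malignant > 1))) {
    stop_input("patch likelihoods must lie in [0, 1]")
  }
  if (length(row) != length(p_malignant) ||
      length(col) != length(p_malignant)) {
    stop_input("row/col must match the number of likelihoods")
  }
  structure(list(slide_id = as.character(slide_id),
                 p_malignant = p_malignant,
                 row = as.integer(row), col = as.integer(col)),
            class = "likelihood_bag")
}

#' @export
length.likelihood_bag <- function(x) length(x$p_malignant)

#' @export
print.likelihood_bag <- function(x, ...) {
  cat(sprintf("<likelihood_bag> slide %s: %d tiles, mean p = %.3f\n",
              x$slide_id, length(x),
              if (length(x)) mean(x$p_malignant) else NA_real_))
  invisible(x)
}

#' Per-slide bag of patch feature embeddings
#'
#' @param slide_id Character scalar.
#' @param features Numeric matrix, one row per tile; all rows share the
#'   extractor's dimension (768 for the ViT-style contract).
#' @return Object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features) {
  features <- as.matrix(features)
  if (!is.numeric(features) || any(!is.finite(features))) {
    stop_input("feature bag must be a finite numeric matrix")
  }
  structure(list(slide_id = as.character(slide_id), features = features),
            class = "feature_bag")
}

#' @export
dim.feature_bag <- function(x) dim(x$features)
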