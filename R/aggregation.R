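# Slide-level feature construction from patch likelihoods: the Patch
# Likelihood Histogram (PLH) and the TF-IDF bag-of-words over discretized
# likelihood "words", plus their fusion.
#
# Both pipelines share one discretization: equal-width bins on [0, 1]
# whose last bin is right-closed so a likelihood of exactly 1 is counted.

#' Equal-width bin edges on the unit interval
#'
#' @param n_bins Number of bins (>= 2).
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
plh_bin_edges <- function(n_bins = 10L) {
  if (n_bins < 2) stop_input("need at least 2 likelihood bins")
  seq(0, 1, length.out = n_bins + 1L)
}

bin_index <- function(p, edges) {
  # half-open [e_i, e_{i+1}) bins, last bin closed at 1
  i <- findInterval(p, edges, rightmost.closed = TRUE, left.open = FALSE)
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

#' Patch Likelihood Histogram of one slide
#'
#' Discretizes a slide's patch likelihoods into equal-width bins and
#' normalizes counts by the number of tiles, yielding the slide's PLH
#' representation (entries sum to 1).
#'
#' @param bag A [likelihood_bag()]; must be non-empty.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Numeric vector of length `n_bins`, named `plh_0` ...
#' @export
plh_vector <- function(bag, n_bins = 10L) {
  stopifnot(inherits(bag, "likelihood_bag"))
  if (length(bag) == 0L) stop_input("empty bag: slide is unscorable")
  edges <- plh_bin_edges(n_bins)
  counts <- tabulate(bin_index(bag$p_malignant, edges), nbins = n_bins)
  h <- counts / length(bag)
  names(h) <- paste0("plh_", seq_len(n_bins) - 1L)
  h
}

#' Map a slide's patches to likelihood-bin words
#'
#' Each patch becomes the id of the likelihood bin it falls in; the
#' slide becomes a word-count vector over that vocabulary (the
#' bag-of-words view of the same discretization that PLH uses).
#'
#' @param bag A [likelihood_bag()].
#' @param edges Bin edges from [plh_bin_edges()].
#' @return Integer count vector, one entry per bin (word), named
#'   `bin0`, `bin1`, ...; counts sum to the number of tiles.
#' @export
tokenize <- function(bag, edges = plh_bin_edges()) {
  stopifnot(inherits(bag, "likelihood_bag"))
  n_words <- length(edges) - 1L
  counts <- tabulate(bin_index(bag$p_malignant, edges), nbins = n_words)
  names(counts) <- paste0("bin", seq_len(n_words) - 1L)
  counts
}

#' Fit a TF-IDF model on a training corpus of word counts
#'
#' Term frequency is the within-slide proportion of each word; inverse
#' document frequency uses the smoothed form
#' \eqn{\mathrm{idf}(t) = \ln((1+N)/(1+\mathrm{df}(t))) + 1}, so a word
#' present in every slide gets the minimum weight 1 and unseen words
#' stay finite.  Vocabulary and idf are fit on the training corpus only
#' and then applied unchanged to held-out slides.
#'
#' @param counts_matrix Integer matrix, slides x words (as produced by
#'   [tokenize()] row-bound over slides).
#' @return List of class `tfidf_model` with `idf` and `vocabulary`.
#' @export
tfidf_fit <- function(counts_matrix) {
  counts_matrix <- rbind(counts_matrix)
  n_slides <- nrow(counts_matrix)
  if (n_slides < 1L) stop_input("TF-IDF needs at least one training slide")
  df <- colSums(counts_matrix > 0)
  idf <- log((1 + n_slides) / (1 + df)) + 1
  structure(list(idf = idf,
                 vocabulary = colnames(counts_matrix) %||%
                   paste0("bin", seq_along(idf) - 1L),
                 n_train = n_slides),
            class = "tfidf_model")
}

#' Apply a fitted TF-IDF model to slides
#'
#' @param model A `tfidf_model` from [tfidf_fit()].
#' @param counts_matrix Slides x words count matrix over the same
#'   vocabulary (words outside the fitted vocabulary are not
#'   representable here because the vocabulary is the fixed set of
#'   likelihood bins).
#' @return Slides x words matrix of L2-normalized tf-idf weights.
#' @export
tfidf_apply <- function(model, counts_matrix) {
  stopifnot(inherits(model, "tfidf_model"))
  counts_matrix <- rbind(counts_matrix)
  if (ncol(counts_matrix) != length(model$idf)) {
    stop_input("word-count matrix does not match the fitted vocabulary")
  }
  totals <- rowSums(counts_matrix)
  tf <- counts_matrix / ifelse(totals > 0, totals, 1)
  x <- sweep(tf, 2L, model$idf, `*`)
  norms <- sqrt(rowSums(x^2))
  x <- x / ifelse(norms > 0, norms, 1)
  colnames(x) <- paste0("bow_", seq_len(ncol(x)) - 1L)
  x
}

#' Fuse PLH and bag-of-words blocks into one slide feature vector
#'
#' @param plh PLH vector for the slide.
#' @param bow TF-IDF vector for the slide.
#' @return Concatenated vector, PLH block first.
#' @export
fuse_features <- function(plh, bow) {
  if (is.null(plh) || is.null(bow) || !length(plh) || !length(bow)) {
    stop_input("slide is missing one of the two feature blocks")
  }
  c(plh, bow)
}

#' Build the fused slide feature matrix for a corpus of likelihood bags
#'
#' Runs the full aggregation stage: PLH per slide, bag-of-words
#' tokenization, TF-IDF fitted on the training slides only and applied
#' to all, then fusion.  This is the step that turns patch-level
#' predictions into WSI-level features.
#'
#' @param bags List of [likelihood_bag()].
#' @param n_bins Number of likelihood bins shared by PLH and BoW.
#' @param train_idx Integer indices of training slides used to fit the
#'   idf weights (default: all slides).
#' @return List with `features` (slides x (2*n_bins) matrix, rownames =
#'   slide ids), `tfidf` (the fitted model) and `bin_edges`.
#' @export
aggregate_corpus <- function(bags, n_bins = 10L,
                             train_idx = seq_along(bags)) {
  if (!length(bags)) stop_input("empty corpus")
  edges <- plh_bin_edges(n_bins)
  plh <- t(vapply(bags, plh_vector, numeric(n_bins), n_bins = n_bins))
  counts <- t(vapply(bags, tokenize, integer(n_bins), edges = edges))
  model <- tfidf_fit(counts[train_idx, , drop = FALSE])
  bow <- tfidf_apply(model, counts)
  features <- cbind(plh, bow)
  rownames(features) <- vapply(bags, `[[`, character(1), "slide_id")
  list(features = features, tfidf = model, bin_edges = edges)
}
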