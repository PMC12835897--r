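# Shared fixtures and independent oracles, all built in code.

# O(n^2) Mann-Whitney AUC oracle: fraction of positive/negative pairs
# ranked correctly, ties counting one half.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# brute-force equal-width histogram on [0,1], last bin right-closed
hist_bruteforce <- function(p, n_bins) {
  counts <- numeric(n_bins)
  for (v in p) {
    b <- min(floor(v * n_bins) + 1, n_bins)
    counts[b] <- counts[b] + 1
  }
  counts / length(p)
}

# all-pairs greedy correlation filter oracle (keeps earlier index)
pearson_filter_oracle <- function(x, r_thresh) {
  p <- ncol(x)
  dropped <- rep(FALSE, p)
  for (i in seq_len(p - 1)) {
    if (dropped[i]) next
    for (j in (i + 1):p) {
      if (dropped[j]) next
      r <- suppressWarnings(stats::cor(x[, i], x[, j]))
      if (is.finite(r) && abs(r) >= r_thresh) dropped[j] <- TRUE
    }
  }
  which(!dropped)
}

# a flat-color RGB tile
solid_tile <- function(rgb, size = 8) {
  array(rep(rgb, each = size * size), dim = c(size, size, 3))
}

# corpus of single-texture tiles from the slide simulator's texture
# model, with known class labels
make_texture_corpus <- function(n, seed, tile_size = 32) {
  tp <- slidewise:::default_texture_params()
  labels <- withr::with_seed(seed, sample(rep(0:1, length.out = n)))
  tiles <- lapply(seq_len(n), function(i) {
    par <- if (labels[i] == 1) tp$malignant else tp$benign
    withr::with_seed(seed * 10000 + i,
                     slidewise:::render_tile(par, tile_size))
  })
  list(tiles = tiles, labels = labels)
}

# synthetic two-stain image with known basis and concentrations
make_stain_image <- function(W, seed = 1, side = 64, sparse = TRUE) {
  n <- side * side
  H <- withr::with_seed(seed, {
    h <- rbind(stats::rexp(n, 1 / 0.8), stats::rexp(n, 1 / 0.6))
    if (sparse) {
      mask <- stats::rbinom(n, 1, 0.5)
      h[1, mask == 1] <- h[1, mask == 1] * 0.1
      h[2, mask == 0] <- h[2, mask == 0] * 0.1
    }
    h
  })
  V <- W %*% H
  list(image = array(t(od_to_rgb(V)) / 255, dim = c(side, side, 3)),
       W = W, H = H)
}

unit_cols <- function(W) sweep(W, 2, sqrt(colSums(W^2)), "/")
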