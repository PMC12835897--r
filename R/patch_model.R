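# Patch-level probabilistic classifier and feature extractor.
#
# The trainable default is a small multilayer perceptron over
# block-averaged tile pixels, trained with minibatch SGD on the
# cross-entropy loss (learning rate 0.001, batch size 32, 20 epochs by
# default).  Block averaging to a 16 x 16 x 3 grid preserves the two
# properties that distinguish tissue textures at this scale -- channel
# color statistics and coarse spatial frequency -- while keeping
# training fast on a single CPU.  The extractor surface is
# architecture-agnostic: anything exposing predict_proba() and
# embed_patches() can stand behind it, including the fixed
# random-projection stub that fulfils the 768-dimensional
# ViT-style feature contract.

#' Training configuration for the patch classifier
#'
#' Defaults follow the common deep-learning recipe for patch
#' classifiers on frozen-section tiles: stochastic gradient descent on
#' cross-entropy with learning rate 0.001, batch size 32, 20 epochs.
#'
#' @param learning_rate SGD step size (> 0).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (>= 1).
#' @param hidden Integer vector of the two hidden-layer widths; the
#'   second hidden layer is the embedding exposed by
#'   [embed_patches()].
#' @param input_size Side of the block-averaged input grid (input
#'   dimension is `3 * input_size^2`).
#' @param seed Integer seed (initialization and batch order).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         epochs = 20L, hidden = c(64L, 32L),
                         input_size = 16L, seed = 1L) {
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (length(hidden) != 2L || any(hidden < 1)) {
    stop_config("hidden must give two positive layer widths")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 hidden = as.integer(hidden),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# block-average one tile to input_size x input_size x 3 and flatten
downsample_tile <- function(tile, input_size) {
  d <- dim(tile)
  if (length(d) != 3L || d[3] != 3L) stop_input("tile must be H x W x 3")
  row_bin <- ceiling(seq_len(d[1]) / (d[1] / input_size))
  col_bin <- ceiling(seq_len(d[2]) / (d[2] / input_size))
  out <- vapply(1:3, function(ch) {
    m <- rowsum(tile[, , ch], row_bin)
    m <- t(rowsum(t(m), col_bin))
    m / tabulate(row_bin)[row(m)] / tabulate(col_bin)[col(m)]
  }, matrix(0, input_size, input_size))
  as.numeric(out)
}

#' Turn a list of tiles into the classifier's input matrix
#'
#' @param tiles List of H x W x 3 arrays (uniform size) or an already
#'   featurized numeric matrix (returned as is).
#' @param input_size Block-averaging grid side.
#' @return Numeric matrix, tiles x `3 * input_size^2`.
#' @export
featurize_tiles <- function(tiles, input_size = 16L) {
  if (is.matrix(tiles)) return(tiles)
  if (!length(tiles)) {
    return(matrix(numeric(0), 0L, 3L * input_size^2))
  }
  sizes <- vapply(tiles, function(t) paste(dim(t), collapse = "x"),
                  character(1))
  if (length(unique(sizes)) != 1L) {
    stop_input("tiles must share one fixed size; got ",
               paste(unique(sizes), collapse = ", "))
  }
  t(vapply(tiles, downsample_tile, numeric(3L * input_size^2),
           input_size = input_size))
}

relu <- function(x) x * (x > 0)

mlp_forward <- function(m, x) {
  z1 <- sweep(x %*% m$W1, 2L, m$b1, `+`); a1 <- relu(z1)
  z2 <- sweep(a1 %*% m$W2, 2L, m$b2, `+`); a2 <- relu(z2)
  z3 <- sweep(a2 %*% m$W3, 2L, m$b3, `+`)
  z3 <- z3 - apply(z3, 1L, max)
  p <- exp(z3); p <- p / rowSums(p)
  list(a1 = a1, a2 = a2, p = p)
}

#' Train the patch classifier
#'
#' Minibatch SGD on the softmax cross-entropy; the run is fully
#' deterministic given `cfg$seed` (weight initialization and epoch
#' shuffles included) and logs the mean training loss per epoch.
#' Input standardization constants (per-feature mean/sd) are computed
#' on the training tiles only and stored in the model, so inference
#' applies the identical preprocessing.
#'
#' @param tiles List of tile arrays or a featurized matrix (see
#'   [featurize_tiles()]).
#' @param labels Binary 0/1 patch labels.
#' @param cfg A [train_config()].
#' @return Object of class `patch_mlp` exposing [predict_proba()] and
#'   [embed_patches()]; field `loss_per_epoch` holds the training
#'   curve.
#' @export
train_patch_classifier <- function(tiles, labels, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  x <- featurize_tiles(tiles, cfg$input_size)
  y <- as.integer(labels)
  if (nrow(x) != length(y)) stop_input("tiles/labels length mismatch")
  if (length(unique(y)) < 2L) {
    stop_input("training set contains a single class")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr, `-`), 2L, scl, `/`)
  d <- ncol(xs); h1 <- cfg$hidden[1]; h2 <- cfg$hidden[2]
  n <- nrow(xs)
  m <- with_seed(cfg$seed, list(
    W1 = matrix(stats::rnorm(d * h1, sd = sqrt(2 / d)), d, h1),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(stats::rnorm(h2 * 2L, sd = sqrt(2 / h2)), h2, 2L),
    b3 = numeric(2L)))
  y_onehot <- cbind(1 - y, y)
  loss_per_epoch <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(child_seed(cfg$seed, ep), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xs[idx, , drop = FALSE]
      yb <- y_onehot[idx, , drop = FALSE]
      fw <- mlp_forward(m, xb)
      ep_loss <- ep_loss - sum(yb * log(pmax(fw$p, 1e-12)))
      nb <- length(idx)
      d3 <- (fw$p - yb) / nb
      g_w3 <- crossprod(fw$a2, d3); g_b3 <- colSums(d3)
      d2 <- (d3 %*% t(m$W3)) * (fw$a2 > 0)
      g_w2 <- crossprod(fw$a1, d2); g_b2 <- colSums(d2)
      d1 <- (d2 %*% t(m$W2)) * (fw$a1 > 0)
      g_w1 <- crossprod(xb, d1); g_b1 <- colSums(d1)
      lr <- cfg$learning_rate
      m$W3 <- m$W3 - lr * g_w3; m$b3 <- m$b3 - lr * g_b3
      m$W2 <- m$W2 - lr * g_w2; m$b2 <- m$b2 - lr * g_b2
      m$W1 <- m$W1 - lr * g_w1; m$b1 <- m$b1 - lr * g_b1
    }
    loss_per_epoch[ep] <- ep_loss / n
  }
  structure(c(m, list(center = ctr, scale = scl,
                      input_size = cfg$input_size,
                      loss_per_epoch = loss_per_epoch,
                      cfg = cfg)),
            class = "patch_mlp")
}

model_input <- function(model, tiles) {
  x <- featurize_tiles(tiles, model$input_size)
  if (ncol(x) != length(model$center)) {
    stop_input("tile feature dimension does not match the model")
  }
  sweep(sweep(x, 2L, model$center, `-`), 2L, model$scale, `/`)
}

#' Per-patch class probabilities
#'
#' @param model A fitted classifier (e.g. from
#'   [train_patch_classifier()]).
#' @param tiles Tiles as in [featurize_tiles()].
#' @return Matrix tiles x 2 with columns `benign`, `malignant`; rows
#'   sum to 1.
#' @export
predict_proba <- function(model, tiles) UseMethod("predict_proba")

#' @export
predict_proba.patch_mlp <- function(model, tiles) {
  x <- model_input(model, tiles)
  if (!nrow(x)) {
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("benign", "malignant"))))
  }
  p <- mlp_forward(model, x)$p
  dimnames(p) <- list(NULL, c("benign", "malignant"))
  p
}

#' Penultimate-layer embeddings of patches
#'
#' @inheritParams predict_proba
#' @return Matrix tiles x d (d = second hidden width for the MLP; 768
#'   for the ViT-contract stub), with attribute `"dim"` recording d.
#' @export
embed_patches <- function(model, tiles) UseMethod("embed_patches")

#' @export
embed_patches.patch_mlp <- function(model, tiles) {
  x <- model_input(model, tiles)
  e <- if (nrow(x)) mlp_forward(model, x)$a2 else
    matrix(numeric(0), 0L, ncol(model$W2))
  attr(e, "dim_meta") <- ncol(model$W2)
  e
}

#' Score a tiled slide into a likelihood bag
#'
#' Scores every tissue tile of a slide regardless of training-time
#' discards (heatmaps and slide aggregation want full coverage).
#'
#' @param model Patch classifier.
#' @param raster Slide raster (H x W x 3).
#' @param tiles Tile-record data frame from [tile_slide()].
#' @param tissue_only Score only tissue tiles (default TRUE).
#' @return A [likelihood_bag()] for the slide.
#' @export
score_slide <- function(model, raster, tiles, tissue_only = TRUE) {
  if (tissue_only) tiles <- tiles[tiles$tissue, , drop = FALSE]
  px <- lapply(seq_len(nrow(tiles)), function(i) {
    tile_pixels(raster, tiles[i, ])
  })
  p <- predict_proba(model, px)
  likelihood_bag(unique(tiles$slide_id) %||% "slide",
                 p[, "malignant"], row = tiles$row, col = tiles$col)
}

#' Fixed random-projection feature extractor (ViT-style contract)
#'
#' A deterministic, training-free extractor emitting `dim`-dimensional
#' per-patch features (default 768, matching the transformer
#' feature-extractor contract) via a fixed seeded Gaussian projection
#' of the block-averaged tile pixels followed by tanh.  It exercises
#' every downstream consumer of feature bags without any pretrained
#' weights.
#'
#' @param dim Output dimension (default 768).
#' @param input_size Block-averaging grid side.
#' @param seed Seed fixing the projection.
#' @return Object of class `stub_extractor` usable with
#'   [embed_patches()].
#' @export
stub_extractor <- function(dim = 768L, input_size = 16L, seed = 1L) {
  if (dim < 1) stop_config("dim must be >= 1")
  d_in <- 3L * as.integer(input_size)^2
  P <- with_seed(seed, matrix(stats::rnorm(d_in * dim, sd = 1 / sqrt(d_in)),
                              d_in, dim))
  structure(list(P = P, input_size = as.integer(input_size),
                 dim = as.integer(dim)),
            class = "stub_extractor")
}

#' @export
embed_patches.stub_extractor <- function(model, tiles) {
  x <- featurize_tiles(tiles, model$input_size)
  e <- tanh(x %*% model$P)
  attr(e, "dim_meta") <- model$dim
  e
}
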