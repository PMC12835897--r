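# Weakly supervised slide classification from per-patch feature bags:
# a multiple-instance head that pools a bag of instance embeddings into
# one slide embedding (arithmetic mean, or a learned attention-weighted
# convex combination) and classifies it with a logistic layer trained
# on cross-entropy.

#' Pooling specification for the bag head
#'
#' @param method `"mean"` (default: the simplest faithful reading of
#'   feeding all patches of a slide into the slide-level predictor) or
#'   `"attention"` (learned tanh-attention convex combination, which
#'   additionally yields per-patch weights for heatmapping).
#' @param attention_hidden Hidden width of the attention scorer.
#' @param max_instances Optional cap per bag; larger bags are
#'   subsampled with the training seed.
#' @param seed Integer seed.
#' @return Object of class `bag_pool_spec`.
#' @export
bag_pool_spec <- function(method = c("mean", "attention"),
                          attention_hidden = 32L,
                          max_instances = NULL, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method,
                 attention_hidden = as.integer(attention_hidden),
                 max_instances = max_instances,
                 seed = as.integer(seed)),
            class = "bag_pool_spec")
}

attention_scores <- function(H, V, w) {
  t_mat <- tanh(H %*% V)
  s <- as.numeric(t_mat %*% w)
  s <- s - max(s)
  a <- exp(s); a <- a / sum(a)
  list(t = t_mat, a = a)
}

#' Pool a feature bag into one slide embedding
#'
#' Mean pooling averages instance rows; attention pooling forms a
#' learned convex combination (weights non-negative, summing to 1).
#' Both are permutation invariant, and a bag of identical rows pools to
#' that row under either method.
#'
#' @param bag A [feature_bag()]; must be non-empty.
#' @param pooler A [bag_pool_spec()] (attention uses seeded untrained
#'   parameters) or a fitted `bag_head` model.
#' @return List with `embedding` (length-d vector) and `weights`
#'   (per-instance convex weights; uniform for mean pooling).
#' @export
pool_bag <- function(bag, pooler) {
  stopifnot(inherits(bag, "feature_bag"))
  H <- bag$features
  n <- nrow(H)
  if (n == 0L) stop_input("cannot pool an empty bag")
  if (inherits(pooler, "bag_pool_spec") && pooler$method == "attention") {
    d <- ncol(H); k <- pooler$attention_hidden
    init <- with_seed(pooler$seed, list(
      V = matrix(stats::rnorm(d * k, sd = 1 / sqrt(d)), d, k),
      w = stats::rnorm(k, sd = 1 / sqrt(k))))
    pooler <- list(method = "attention", V = init$V, w = init$w)
  }
  if (is.list(pooler) && identical(pooler$method, "attention")) {
    at <- attention_scores(H, pooler$V, pooler$w)
    list(embedding = as.numeric(at$a %*% H), weights = at$a)
  } else {
    list(embedding = colMeans(H), weights = rep(1 / n, n))
  }
}

adam_step <- function(state, name, grad, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$m[[name]] <- b1 * state$m[[name]] + (1 - b1) * grad
  state$v[[name]] <- b2 * state$v[[name]] + (1 - b2) * grad^2
  mh <- state$m[[name]] / (1 - b1^t)
  vh <- state$v[[name]] / (1 - b2^t)
  state$par[[name]] <- state$par[[name]] - lr * mh / (sqrt(vh) + eps)
  state
}

#' Train the bag-pooling slide head
#'
#' Minimizes the cross-entropy of slide labels over pooled bag
#' embeddings.  Mean pooling trains the logistic layer only; attention
#' pooling jointly trains the attention scorer and the logistic layer
#' (full-batch Adam, deterministic given `spec$seed`).
#'
#' @param bags List of [feature_bag()] sharing one dimension.
#' @param labels Binary 0/1 slide labels.
#' @param spec A [bag_pool_spec()].
#' @param epochs Training epochs (default 200).
#' @param lr Learning rate (default 0.01).
#' @param l2 L2 weight on the logistic layer (default 0.05; the head
#'   operates in high dimension with order-10^2 slides, so ridge-style
#'   shrinkage carries most of the generalization burden).
#' @return Object of class `bag_head` exposing [predict_bag()]; field
#'   `weights_of(bag)` behavior is available through
#'   [pool_bag()] with the fitted model.
#' @export
train_bag_head <- function(bags, labels, spec = bag_pool_spec(),
                           epochs = 200L, lr = 0.01, l2 = 0.05) {
  stopifnot(inherits(spec, "bag_pool_spec"))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop_input("need both classes to train")
  dims <- vapply(bags, function(b) ncol(b$features), integer(1))
  if (length(unique(dims)) != 1L) {
    stop_input("bags disagree on instance dimension")
  }
  d <- dims[1]
  H_list <- lapply(seq_along(bags), function(i) {
    H <- bags[[i]]$features
    cap <- spec$max_instances
    if (!is.null(cap) && nrow(H) > cap) {
      H <- H[with_seed(child_seed(spec$seed, i),
                       sample.int(nrow(H), cap)), , drop = FALSE]
    }
    H
  })
  n <- length(bags)
  k <- spec$attention_hidden
  par <- with_seed(spec$seed, list(
    V = matrix(stats::rnorm(d * k, sd = 1 / sqrt(d)), d, k),
    w = stats::rnorm(k, sd = 1 / sqrt(k)),
    beta = numeric(d), b = 0))
  state <- list(par = par,
                m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  attention <- spec$method == "attention"
  loss_hist <- numeric(epochs)
  for (it in seq_len(epochs)) {
    g <- list(V = state$par$V * 0, w = state$par$w * 0,
              beta = state$par$beta * 0, b = 0)
    loss <- 0
    for (i in seq_len(n)) {
      H <- H_list[[i]]
      if (attention) {
        at <- attention_scores(H, state$par$V, state$par$w)
        a <- at$a; t_mat <- at$t
        z <- as.numeric(a %*% H)
      } else {
        z <- colMeans(H)
      }
      logit <- sum(z * state$par$beta) + state$par$b
      p <- 1 / (1 + exp(-logit))
      loss <- loss - (y[i] * log(max(p, 1e-12)) +
                      (1 - y[i]) * log(max(1 - p, 1e-12)))
      dlogit <- (p - y[i]) / n
      g$beta <- g$beta + dlogit * z
      g$b <- g$b + dlogit
      if (attention) {
        dz <- dlogit * state$par$beta
        da <- as.numeric(H %*% dz)
        ds <- a * (da - sum(a * da))
        g$w <- g$w + as.numeric(crossprod(t_mat, ds))
        dpre <- (ds %o% state$par$w) * (1 - t_mat^2)
        g$V <- g$V + crossprod(H, dpre)
      }
    }
    g$beta <- g$beta + 2 * l2 * state$par$beta
    loss_hist[it] <- loss / n + l2 * sum(state$par$beta^2)
    for (nm in if (attention) c("V", "w", "beta", "b") else
                c("beta", "b")) {
      state <- adam_step(state, nm, g[[nm]], lr, it)
    }
  }
  structure(list(method = spec$method, V = state$par$V,
                 w = state$par$w, beta = state$par$beta,
                 b = state$par$b, spec = spec, dim = d,
                 loss_per_epoch = loss_hist),
            class = c("bag_head"))
}

#' Slide probabilities (and attention weights) from a fitted bag head
#'
#' @param model A `bag_head` from [train_bag_head()].
#' @param bags List of [feature_bag()].
#' @return List with `p` (per-bag positive-class probabilities, named
#'   by slide id) and `weights` (per-bag instance weight vectors).
#' @export
predict_bag <- function(model, bags) {
  stopifnot(inherits(model, "bag_head"))
  pool_model <- list(method = model$method, V = model$V, w = model$w)
  res <- lapply(bags, function(b) {
    pl <- pool_bag(b, pool_model)
    logit <- sum(pl$embedding * model$beta) + model$b
    list(p = 1 / (1 + exp(-logit)), w = pl$weights)
  })
  list(p = stats::setNames(vapply(res, `[[`, numeric(1), "p"),
                           vapply(bags, `[[`, character(1), "slide_id")),
       weights = lapply(res, `[[`, "w"))
}
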