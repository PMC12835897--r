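# Slide-level dataset construction (class balancing, stratified
# splitting) and the three slide classifiers (logistic regression, SVM,
# random forest) tuned by inner cross-validated grid search.

#' Balance classes by undersampling the majority class
#'
#' Keeps every minority-class slide and a seeded random subset of the
#' majority class, mirroring the common practice of trimming a heavily
#' imbalanced cohort (e.g. 301 mutated vs 29 wild-type slides reduced to
#' 31 + 29 = 60) before splitting.
#'
#' @param labels Named binary vector (names = slide ids) or unnamed
#'   vector (ids default to positions).
#' @param n_keep_majority Number of majority-class slides to retain.
#' @param seed Integer seed.
#' @return Character vector of kept slide ids (minority first, then the
#'   sampled majority ids in sampling order).
#' @export
undersample_balance <- function(labels, n_keep_majority, seed = 1L) {
  ids <- names(labels) %||% as.character(seq_along(labels))
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) != 2L) stop_input("labels must contain exactly 2 classes")
  major <- names(tab)[which.max(tab)]
  major_ids <- ids[labels == as.integer(major)]
  minor_ids <- ids[labels != as.integer(major)]
  if (n_keep_majority > length(major_ids)) {
    stop_input("cannot keep ", n_keep_majority, " of ",
               length(major_ids), " majority slides")
  }
  kept_major <- with_seed(seed,
                          sample(major_ids, n_keep_majority,
                                 replace = FALSE))
  c(minor_ids, kept_major)
}

#' Stratified train/test split with largest-remainder allocation
#'
#' Splits slide ids so the training set holds `round(N * ratio)` slides
#' and each class contributes its largest-remainder share, keeping
#' per-class proportions within one slide of the global ones.  For a
#' 60-slide cohort at ratio 0.7 this yields exactly 42 training and 18
#' test slides.
#'
#' @param ids Character vector of slide ids.
#' @param labels Binary labels aligned with `ids`.
#' @param ratio Training fraction in (0, 1) (default 0.7).
#' @param seed Integer seed for the within-class shuffles.
#' @return List of class `split_plan` with `train_ids`, `test_ids`,
#'   `ratio`, `seed`.
#' @export
stratified_split <- function(ids, labels, ratio = 0.7, seed = 1L) {
  ids <- as.character(ids)
  if (length(ids) != length(labels)) stop_input("ids/labels length mismatch")
  if (!(ratio > 0 && ratio < 1)) {
    stop_input("ratio must lie strictly inside (0, 1)")
  }
  classes <- split(ids, as.integer(labels))
  if (any(lengths(classes) < 2L)) {
    stop_input("every class needs >= 2 slides to stratify")
  }
  n_train <- round(length(ids) * ratio)
  exact <- lengths(classes) * ratio
  base <- floor(exact)
  remainder <- exact - base
  short <- n_train - sum(base)
  # hand the leftover slots to the classes with the largest remainders
  extra <- integer(length(classes))
  if (short > 0) {
    extra[order(remainder, decreasing = TRUE)[seq_len(short)]] <- 1L
  } else if (short < 0) {
    give_back <- order(remainder)[seq_len(-short)]
    extra[give_back] <- -1L
  }
  take <- base + extra
  train_ids <- character(0)
  for (k in seq_along(classes)) {
    shuffled <- with_seed(child_seed(seed, k), sample(classes[[k]]))
    train_ids <- c(train_ids, shuffled[seq_len(take[k])])
  }
  structure(list(train_ids = train_ids,
                 test_ids = setdiff(ids, train_ids),
                 ratio = ratio, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (ratio %.2f)\n",
              length(x$train_ids), length(x$test_ids), x$ratio))
  invisible(x)
}

default_grids <- function() {
  list(
    lr  = list(lambda = 10^seq(2, -2, length.out = 9)),  # inverse-C grid
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c(NA, 0.01, 0.1)),  # NA = 1/p heuristic
    rf  = expand.grid(ntree = c(100L, 300L),
                      maxnodes = c(NA, 8L, 32L))
  )
}

cv_fold_ids <- function(y, k, seed) {
  # stratified fold assignment
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- with_seed(child_seed(seed, as.integer(cls) + 17L),
                           sample(rep_len(seq_len(k), length(idx))))
  }
  fold
}

fit_one_family <- function(family, x, y, grid, folds, seed) {
  fit_fun <- switch(family,
    lr = function(xtr, ytr, par) {
      glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                     lambda = c(par$lambda * 2, par$lambda),
                     standardize = FALSE)
    },
    svm = function(xtr, ytr, par) {
      gamma <- if (is.na(par$gamma)) 1 / ncol(xtr) else par$gamma
      e1071::svm(xtr, factor(ytr, levels = c(0, 1)), kernel = "radial",
                 cost = par$cost, gamma = gamma, probability = TRUE)
    },
    rf = function(xtr, ytr, par) {
      if (is.na(par$maxnodes)) {
        randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                   ntree = par$ntree)
      } else {
        randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                   ntree = par$ntree,
                                   maxnodes = min(par$maxnodes, nrow(xtr)))
      }
    })
  pred_fun <- switch(family,
    lr = function(fit, xte, par) {
      as.numeric(stats::predict(fit, xte, s = par$lambda,
                                type = "response"))
    },
    svm = function(fit, xte, par) {
      pr <- attr(stats::predict(fit, xte, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    },
    rf = function(fit, xte, par) {
      as.numeric(stats::predict(fit, xte, type = "prob")[, "1"])
    })

  grid_rows <- if (is.data.frame(grid)) seq_len(nrow(grid)) else
    seq_along(grid[[1]])
  par_at <- function(i) {
    if (is.data.frame(grid)) as.list(grid[i, , drop = FALSE])
    else stats::setNames(list(grid[[1]][i]), names(grid)[1])
  }
  cv_auc <- vapply(grid_rows, function(i) {
    par <- par_at(i)
    scores <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- with_seed(child_seed(seed, 100L + f),
                       fit_fun(x[tr, , drop = FALSE], y[tr], par))
      scores[!tr] <- pred_fun(fit, x[!tr, , drop = FALSE], par)
    }
    if (length(unique(y)) < 2L) return(NA_real_)
    roc_auc(scores, y)$auc
  }, numeric(1))
  best <- which.max(cv_auc)
  par <- par_at(best)
  final <- with_seed(child_seed(seed, 999L), fit_fun(x, y, par))
  list(family = family, fit = final, params = par,
       cv_auc = cv_auc[best],
       predict = function(newx) pred_fun(final, as.matrix(newx), par))
}

#' Train the slide-level classifier panel with inner-CV parameter search
#'
#' For each requested family (regularized logistic regression, RBF SVM
#' with Platt-scaled probabilities, random forest) a small hyperparameter
#' grid is searched by stratified inner cross-validation on the training
#' split only (scored by AUC), then the winning configuration is refit on
#' the full training split.
#'
#' @param x_train Selected-feature matrix (training slides).
#' @param y_train Binary 0/1 labels.
#' @param families Subset of `c("lr", "svm", "rf")`.
#' @param inner_folds Inner-CV fold count (default 5).
#' @param seed Integer seed (folds, forests).
#' @param grids Optional replacement for [default_grids()].
#' @return List of class `slide_models`, one fitted entry per family,
#'   each exposing `$predict(newx)` returning malignant-class
#'   probabilities.
#' @export
fit_slide_models <- function(x_train, y_train,
                             families = c("lr", "svm", "rf"),
                             inner_folds = 5L, seed = 1L,
                             grids = default_grids()) {
  x_train <- as.matrix(x_train)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) {
    stop_input("training labels contain a single class")
  }
  if (!ncol(x_train)) stop_input("no features to train on")
  families <- match.arg(families, c("lr", "svm", "rf"),
                        several.ok = TRUE)
  folds <- cv_fold_ids(y_train, inner_folds, seed)
  models <- lapply(families, function(f) {
    fit_one_family(f, x_train, y_train, grids[[f]], folds, seed)
  })
  names(models) <- families
  structure(models, class = "slide_models")
}

#' Score slides with every fitted family
#'
#' @param models A `slide_models` object.
#' @param x_test Feature matrix of test slides.
#' @return Matrix of probabilities, slides x families.
#' @export
predict_slide_models <- function(models, x_test) {
  stopifnot(inherits(models, "slide_models"))
  x_test <- as.matrix(x_test)
  out <- vapply(models, function(m) m$predict(x_test),
                numeric(nrow(x_test)))
  out <- matrix(out, nrow = nrow(x_test),
                dimnames = list(rownames(x_test), names(models)))
  out
}
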