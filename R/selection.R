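# Feature selection: z-normalization, Pearson correlation filtering and
# sparse selection by cross-validated LASSO (MSE criterion).

#' Fit a z-score scaler on training rows and apply it to train and test
#'
#' Training columns are centered and scaled to unit sample standard
#' deviation; test columns reuse the training mean/sd so no test
#' information leaks into the scaling.  Columns with zero variance on
#' the training split are flagged and passed through centered only.
#'
#' @param x_train,x_test Numeric matrices with identical columns
#'   (`x_test` may be `NULL`).
#' @return List with `train`, `test`, `center`, `scale`, and
#'   `constant` (logical flag per feature).
#' @export
zscore_fit_apply <- function(x_train, x_test = NULL) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2L) stop_input("need >= 2 training rows to scale")
  ctr <- colMeans(x_train)
  sds <- apply(x_train, 2L, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  scl <- ifelse(constant, 1, sds)
  scale_with <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) != length(ctr)) stop_input("column mismatch with scaler")
    sweep(sweep(x, 2L, ctr, `-`), 2L, scl, `/`)
  }
  list(train = scale_with(x_train),
       test = if (!is.null(x_test)) scale_with(x_test),
       center = ctr, scale = scl, constant = constant)
}

#' Drop highly correlated features by a greedy forward scan
#'
#' Features are visited in column order; a feature is dropped when its
#' absolute Pearson correlation with any already-kept feature reaches
#' the threshold, so the earlier-indexed member of each correlated pair
#' survives.  The result is deterministic and all pairwise |r| among
#' kept features are below the threshold.  Constant features have
#' undefined correlation and are treated as uncorrelated (kept).
#'
#' @param x Numeric matrix (rows = slides).
#' @param r_thresh Absolute-correlation threshold (default 0.9; pairs
#'   with |r| >= `r_thresh` are deduplicated).
#' @return Integer vector of kept column indices.
#' @export
pearson_filter <- function(x, r_thresh = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_input("need >= 2 rows to estimate correlations")
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0  # constant columns: undefined r treated as 0
  kept <- integer(0)
  for (j in seq_len(p)) {
    if (sds[j] == 0 || !length(kept) ||
        all(abs(r[j, kept]) < r_thresh)) {
      kept <- c(kept, j)
    }
  }
  kept
}

#' Sparse feature selection by cross-validated LASSO
#'
#' Fits the L1-penalized linear model over a log-spaced lambda path and
#' picks the lambda minimizing k-fold cross-validated mean squared
#' error; features with nonzero coefficients at that lambda are the
#' selected set.  The binary class label is treated as a numeric 0/1
#' response so the tuning criterion is MSE, matching the usual
#' radiomics-style LASSO curve; a logistic variant is available via
#' `family = "binomial"` (tuned by deviance).
#'
#' @param x Scaled feature matrix (training slides only).
#' @param y Binary 0/1 labels.
#' @param k_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda,lambda.min.ratio Path resolution: `nlambda` log-spaced
#'   values descending from the smallest all-zero lambda over
#'   `lambda.min.ratio` decades' span (defaults 100 values, 4 decades).
#' @param family `"gaussian"` (MSE criterion, default) or `"binomial"`.
#' @param rule `"min"` (default: lambda minimizing CV MSE) or `"1se"`
#'   (largest lambda within one standard error of the minimum; sparser,
#'   at the cost of no longer sitting at the MSE minimum).
#' @return List of class `selection_report`: `selected` (column
#'   indices), `coefficients` (named, nonzero at lambda*),
#'   `lambda_star`, `lambda_grid`, `cv_mse`, `cv_se`, `n_selected`.
#' @export
lasso_select <- function(x, y, k_folds = 10L, seed = 1L,
                         nlambda = 100L, lambda.min.ratio = 1e-4,
                         family = c("gaussian", "binomial"),
                         rule = c("min", "1se")) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    warning("constant response: no features selectable")
    return(structure(list(selected = integer(0),
                          coefficients = numeric(0),
                          lambda_star = NA_real_,
                          lambda_grid = numeric(0),
                          cv_mse = numeric(0), cv_se = numeric(0),
                          n_selected = 0L),
                     class = "selection_report"))
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(k_folds), nrow(x))))
  cv <- glmnet::cv.glmnet(x, y, family = family, alpha = 1,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda.min.ratio,
                          foldid = foldid, standardize = FALSE,
                          type.measure = if (family == "gaussian") "mse"
                                         else "deviance")
  s_star <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = s_star))[-1L]
  selected <- which(abs(beta) > 0)
  coefs <- beta[selected]
  names(coefs) <- if (length(selected)) {
    colnames(x)[selected] %||% paste0("f", selected)
  } else character(0)
  structure(list(selected = selected, coefficients = coefs,
                 lambda_star = s_star, lambda_grid = cv$lambda,
                 cv_mse = cv$cvm, cv_se = cv$cvsd,
                 n_selected = length(selected)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("LASSO selection: %d features at lambda* = %.4g\n",
              x$n_selected, x$lambda_star))
  invisible(x)
}

#' Run the full selection stage on a train/test feature split
#'
#' Scaling, correlation filtering and LASSO are all fit on the training
#' split only and applied to the test split, so selection never touches
#' test labels.
#'
#' @param x_train,x_test Feature matrices.
#' @param y_train Training labels (0/1).
#' @param r_thresh Correlation threshold for [pearson_filter()].
#' @param k_folds,seed Passed to [lasso_select()].
#' @return List with reduced `train` and `test` matrices, the kept /
#'   selected indices (relative to the original columns), and the
#'   underlying `selection_report`.
#' @export
select_features <- function(x_train, x_test, y_train, r_thresh = 0.9,
                            k_folds = 10L, seed = 1L) {
  sc <- zscore_fit_apply(x_train, x_test)
  kept <- pearson_filter(sc$train, r_thresh)
  rep <- lasso_select(sc$train[, kept, drop = FALSE], y_train,
                      k_folds = k_folds, seed = seed)
  sel <- if (length(rep$selected)) kept[rep$selected] else kept
  list(train = sc$train[, sel, drop = FALSE],
       test = if (!is.null(sc$test)) sc$test[, sel, drop = FALSE],
       kept_by_corr = kept, selected = sel, report = rep,
       scaler = sc[c("center", "scale", "constant")])
}
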