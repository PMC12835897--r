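test_that("undersampling keeps the minority class and the requested majority count", {
  labels <- stats::setNames(rep(c(1L, 0L), c(301, 29)),
                            paste0("w", 1:330))
  kept <- undersample_balance(labels, 31, seed = 5)
  expect_length(kept, 60)
  expect_equal(sum(labels[kept] == 0L), 29)  # all minority slides kept
  expect_equal(sum(labels[kept] == 1L), 31)
  # determinism and identity
  expect_identical(kept, undersample_balance(labels, 31, seed = 5))
  all_kept <- undersample_balance(labels, 301, seed = 1)
  expect_setequal(all_kept, names(labels))
  expect_error(undersample_balance(labels, 302, seed = 1), "cannot keep")
})

test_that("stratified 7:3 split allocates 42/18 on the balanced cohort", {
  labels <- rep(c(1L, 0L), c(31, 29))
  ids <- paste0("w", 1:60)
  plan <- stratified_split(ids, labels, ratio = 0.7, seed = 2)
  expect_length(plan$train_ids, 42)
  expect_length(plan$test_ids, 18)
  expect_setequal(c(plan$train_ids, plan$test_ids), ids)
  expect_error(stratified_split(ids, labels, ratio = 1), "strictly")
})

test_that("largest-remainder allocation matches a brute-force allocator", {
  brute_alloc <- function(n_by_class, ratio) {
    n_train <- round(sum(n_by_class) * ratio)
    exact <- n_by_class * ratio
    base <- floor(exact)
    short <- n_train - sum(base)
    ord <- order(exact - base, decreasing = TRUE)
    take <- base
    for (k in seq_len(abs(short))) {
      i <- ord[if (short > 0) k else length(ord) - k + 1]
      take[i] <- take[i] + sign(short)
    }
    take
  }
  for (n1 in c(5, 14, 31)) {
    for (n0 in c(5, 17, 29)) {
      for (ratio in c(0.5, 0.7, 0.8)) {
        labels <- rep(c(1L, 0L), c(n1, n0))
        ids <- as.character(seq_along(labels))
        plan <- stratified_split(ids, labels, ratio = ratio, seed = 1)
        got <- table(labels[as.integer(plan$train_ids)])
        want <- brute_alloc(c(n0, n1), ratio)  # class order 0, 1
        expect_equal(as.integer(got[c("0", "1")]), want)
        expect_length(plan$train_ids, round((n0 + n1) * ratio))
        # per-class train share within one slide of the global ratio
        expect_lte(max(abs(want - c(n0, n1) * ratio)), 1)
      }
    }
  }
})

test_that("all model families separate linearly separable features", {
  set.seed(10)
  x <- rbind(matrix(rnorm(60, mean = 0), 30, 2),
             matrix(rnorm(60, mean = 4), 30, 2))
  y <- rep(c(0L, 1L), each = 30)
  models <- fit_slide_models(x, y, seed = 1)
  p <- predict_slide_models(models, x)
  for (fam in c("lr", "svm", "rf")) {
    expect_gte(mean((p[, fam] > 0.5) == y), 0.97)
  }
})

test_that("hyperparameter choice and splits are deterministic in the seed", {
  set.seed(20)
  x <- matrix(rnorm(50 * 4), 50, 4)
  y <- rbinom(50, 1, plogis(x[, 1]))
  m1 <- fit_slide_models(x, y, families = c("lr", "rf"), seed = 9)
  m2 <- fit_slide_models(x, y, families = c("lr", "rf"), seed = 9)
  expect_identical(m1$lr$params, m2$lr$params)
  expect_identical(m1$rf$params, m2$rf$params)
  expect_equal(predict_slide_models(m1, x), predict_slide_models(m2, x))
})

test_that("label-shuffled training yields chance-level test AUC", {
  set.seed(30)
  aucs <- sapply(1:5, function(s) {
    x <- matrix(rnorm(120 * 5), 120, 5)
    y_true <- rbinom(120, 1, 0.5)
    tr <- 1:80; te <- 81:120
    y_shuf <- withr::with_seed(s, sample(y_true[tr]))
    m <- fit_slide_models(x[tr, ], y_shuf, families = "lr", seed = s)
    roc_auc(predict_slide_models(m, x[te, ])[, "lr"], y_true[te])$auc
  })
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_slide_models(x, rep(1L, 10)), "single class")
  expect_error(fit_slide_models(x[, 0], rep(c(0L, 1L), 5)),
               "no features")
})
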