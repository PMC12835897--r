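test_that("benign slides carry no ROI and malignant slides plant one", {
  cfg0 <- slide_sim_config(4, 4, tile_size = 16, malignant_fraction = 0,
                           seed = 1)
  s0 <- simulate_slide(cfg0)
  expect_equal(sum(s0$roi_mask), 0)
  expect_equal(s0$label, 0L)
  expect_equal(dim(s0$raster), c(64, 64, 3))

  cfg1 <- slide_sim_config(4, 4, tile_size = 16,
                           malignant_fraction = 0.25,
                           blank_fraction = 0, seed = 1)
  s1 <- simulate_slide(cfg1)
  expect_equal(s1$label, 1L)
  # brute-force pixel count over the mask: exactly 4 tiles fully covered
  full_tiles <- 0
  for (r in 0:3) for (c in 0:3) {
    sub <- s1$roi_mask[(r * 16 + 1):((r + 1) * 16),
                       (c * 16 + 1):((c + 1) * 16)]
    if (all(sub == 1)) full_tiles <- full_tiles + 1
    else expect_equal(sum(sub), 0)  # mask covers whole tiles or none
  }
  expect_equal(full_tiles, 4)
})

test_that("slide generation is byte-identical under a fixed config and seed", {
  cfg <- slide_sim_config(3, 5, tile_size = 16, malignant_fraction = 0.4,
                          blank_fraction = 0.2, seed = 7)
  a <- simulate_slide(cfg)
  b <- simulate_slide(cfg)
  expect_identical(a$raster, b$raster)
  expect_identical(a$roi_mask, b$roi_mask)
  expect_identical(a$tiles, b$tiles)
  expect_error(slide_sim_config(0, 4), "positive")
})

test_that("likelihood corpus moments match the Beta components", {
  cfg <- likelihood_sim_config(1, n_patches = 10000, class_prior = 0,
                               benign_beta = c(2, 8), seed = 3)
  corp <- simulate_likelihood_corpus(cfg)
  p <- corp$bags[[1]]$p_malignant
  mu <- 2 / 10; v <- (2 * 8) / (10^2 * 11)
  expect_lt(abs(mean(p) - mu), 3 * sqrt(v / 10000))
  expect_lt(abs(stats::var(p) - v), 5 * v / sqrt(10000))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a degenerate rho interval sends every malignant patch to the hot component", {
  cfg <- likelihood_sim_config(4, n_patches = 4000, class_prior = 1,
                               malignant_beta = c(8, 2),
                               rho_range = c(1, 1), seed = 5)
  corp <- simulate_likelihood_corpus(cfg)
  for (b in corp$bags) {
    expect_lt(abs(mean(b$p_malignant) - 0.8), 0.03)  # Beta(8,2) mean
  }
  expect_true(all(unlist(corp$components) == 1L))
})

test_that("corpus bookkeeping: empty corpora, priors and determinism", {
  empty <- simulate_likelihood_corpus(likelihood_sim_config(0))
  expect_length(empty$bags, 0)
  expect_length(empty$labels, 0)
  cfg <- likelihood_sim_config(40, n_patches = c(20, 40), seed = 11)
  c1 <- simulate_likelihood_corpus(cfg)
  c2 <- simulate_likelihood_corpus(cfg)
  expect_equal(sum(c1$labels), 20)  # class_prior 0.5
  expect_identical(lapply(c1$bags, `[[`, "p_malignant"),
                   lapply(c2$bags, `[[`, "p_malignant"))
  expect_error(likelihood_sim_config(5, benign_beta = c(0, 8)),
               "positive")
  expect_error(likelihood_sim_config(5, rho_range = numeric(0)),
               "rho_range")
})

test_that("feature bags plant the closed-form mean-pool separation", {
  sim <- simulate_feature_bags(200, 30, dim = 768, signal_shift = 3,
                               witness_rate = 0.3, seed = 13)
  expect_true(all(vapply(sim$bags, function(b) ncol(b$features),
                         integer(1)) == 768))
  pooled1 <- vapply(sim$bags, function(b) mean(b$features[, 1]),
                    numeric(1))
  gap <- mean(pooled1[sim$labels == 1]) - mean(pooled1[sim$labels == 0])
  # analytic displacement: shift * witness_rate = 0.9
  expect_lt(abs(gap - 0.9), 0.1)
  # witnesses only appear in positive bags
  expect_true(all(!unlist(sim$witness[sim$labels == 0])))
  expect_error(simulate_feature_bags(10, 5, witness_rate = 0), "witness_rate")
  expect_error(simulate_feature_bags(10, 5, dim = 0), "dim")
})

test_that("null-signal bags are exchangeable between classes", {
  sim <- simulate_feature_bags(60, 20, dim = 16, signal_shift = 0,
                               witness_rate = 0.3, seed = 17)
  pooled <- t(vapply(sim$bags, function(b) colMeans(b$features),
                     numeric(16)))
  # two-sample difference on the signal axis is indistinguishable from 0
  d <- mean(pooled[sim$labels == 1, 1]) - mean(pooled[sim$labels == 0, 1])
  se <- sqrt(2 / (20 * 30))
  expect_lt(abs(d), 4 * se)
})

test_that("slide cohorts report the realized lesion fraction", {
  cohort <- simulate_slide_cohort(8, grid_rows = 5, grid_cols = 5,
                                  tile_size = 16, rho_range = c(0.3, 0.6),
                                  blank_fraction = 0.1, seed = 19)
  expect_equal(sum(cohort$labels), 4)
  for (i in seq_along(cohort$slides)) {
    s <- cohort$slides[[i]]
    if (cohort$labels[i] == 1L) {
      expect_equal(s$rho, sum(s$tiles$in_roi) / sum(!s$tiles$blank))
      expect_gt(s$rho, 0.2)
    } else {
      expect_equal(s$rho, 0)
    }
  }
})
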