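# Cross-validated pollution score: fold handling, score arithmetic,
# IVW pooling, weight estimation, data-reuse separation.

test_that("assign_folds partitions with near-equal sizes, deterministically", {
  f <- assign_folds(100, 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  f95 <- assign_folds(95, 10, seed = 2)
  expect_equal(sort(as.integer(table(f95))), c(rep(9L, 5), rep(10L, 5)))
  expect_identical(assign_folds(57, 7, seed = 3), assign_folds(57, 7, seed = 3))
  expect_false(identical(assign_folds(57, 7, seed = 3),
                         assign_folds(57, 7, seed = 4)))
  expect_error(assign_folds(5, 10), "cannot split")
})

test_that("compute_score arithmetic is exact", {
  w <- structure(list(alphas = c(pm25 = 0.02, pm10 = 0.01, no2 = 0.005,
                                 nox = 0.005), normalizer = 100),
                 class = "score_weights")
  expect_identical(compute_score(c(0, 0, 0, 0), w), 0)
  expect_equal(compute_score(c(10, 15, 18, 27), w), 57.5,
               tolerance = 1e-14)
  # equal weights reduce to the unweighted sum
  expect_equal(compute_score(c(1, 1, 1, 1), rep(0.37, 4)), 4,
               tolerance = 1e-14)
  # scale invariance: multiplying alphas by c > 0 changes nothing
  set.seed(701)
  ex <- matrix(runif(40, 5, 30), 10, 4,
               dimnames = list(NULL, c("pm25", "pm10", "no2", "nox")))
  a <- c(0.02, 0.01, 0.005, 0.005)
  expect_equal(compute_score(ex, a), compute_score(ex, 7.3 * a),
               tolerance = 1e-12)
})

test_that("fold weight normalizer follows the formula", {
  # alphas (0.02, 0.01, 0.005, 0.005): normalizer = 4 / 0.04 = 100
  coh <- simulate_cohort(test_config(4000, seed = 11))
  w <- fit_fold_weights(coh, "model1", fold_id = 1)
  expect_equal(w$normalizer, 4 / sum(w$alphas), tolerance = 1e-12)
  # all-equal alphas: score reduces to c * unweighted sum with c = 1
  expect_equal(4 / sum(rep(0.01, 4)), 100)
})

test_that("single truly causal pollutant gets the largest weight", {
  te <- default_true_effects()
  te$true_alphas <- c(pm25 = log(1.3) / 2.3, pm10 = 0, no2 = 0, nox = 0)
  te$score_per_iqr <- log(1.3)
  rk <- unlist(lapply(1:2, function(s) {
    coh <- simulate_cohort(test_config(30000, seed = s, true_effects = te))
    res <- suppressWarnings(run_pollution_score(coh, "model1", seed = s))
    # compare on the per-IQR scale so units are commensurate
    sapply(res$fold_weights, function(w)
      which.max(w$alphas * c(2.3, 3.2, 6.9, 12)))
  }))
  expect_gt(mean(rk == 1), 0.9)
})

test_that("ivw_pool closed forms", {
  # ten identical folds: se shrinks by sqrt(10)
  r <- ivw_pool(rep(0.1, 10), rep(0.2, 10))
  expect_equal(r$beta, 0.1, tolerance = 1e-12)
  expect_equal(r$se, 0.2 / sqrt(10), tolerance = 1e-12)
  # symmetry
  expect_equal(ivw_pool(c(0, 1), c(1, 1))$beta, 0.5, tolerance = 1e-12)
  # hand-worked: (0.2, se 0.1) and (0.4, se 0.2) -> 0.24, se 1/sqrt(125)
  r2 <- ivw_pool(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(r2$beta, 0.24, tolerance = 1e-12)
  expect_equal(r2$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_error(ivw_pool(numeric(0), numeric(0)), "no usable")
  expect_error(ivw_pool(c(0.1), c(0)), "positive")
})

test_that("spearman_matrix basics and degeneracies", {
  set.seed(702)
  x <- rnorm(50)
  m <- spearman_matrix(data.frame(a = x, b = x, c = -x))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_warning(mc <- spearman_matrix(data.frame(a = x, b = rep(1, 50))),
                 "constant")
  expect_true(is.na(mc["a", "b"]))
  expect_error(spearman_matrix(data.frame(a = 1:2, b = 2:1)), "3 subjects")
})

test_that("pipeline enforces data-reuse separation and is reproducible", {
  coh <- simulate_cohort(test_config(6000, seed = 21))
  res <- suppressWarnings(run_pollution_score(coh, "model1", k = 5, seed = 9))
  # refitting fold 3's weights on its training subjects (slow exported path)
  # reproduces the pipeline's weights: the held-out fold contributed nothing
  w3 <- suppressWarnings(
    fit_fold_weights(coh[res$folds != 3, ], "model1", fold_id = 3))
  expect_equal(w3$alphas, res$fold_weights[[3]]$alphas, tolerance = 1e-6)
  # and the held-out association matches the exported operation
  test <- coh[res$folds == 3, ]
  test$score <- res$score[res$folds == 3]
  fr <- suppressWarnings(
    fold_association(test, "model1", res$iqr, res$cuts, fold_id = 3))
  expect_equal(fr$beta_per_iqr, res$fold_results[[3]]$beta_per_iqr,
               tolerance = 1e-8)
  expect_equal(fr$se, res$fold_results[[3]]$se, tolerance = 1e-8)
  # determinism
  res2 <- suppressWarnings(run_pollution_score(coh, "model1", k = 5, seed = 9))
  expect_identical(res$score, res2$score)
  expect_identical(res$pooled, res2$pooled)
})

test_that("pooled quantities respect their structural invariants", {
  coh <- simulate_cohort(test_config(8000, seed = 31))
  res <- suppressWarnings(run_pollution_score(coh, "model1", seed = 5))
  ft <- fold_table(res)
  # pooled se cannot exceed the best single fold
  expect_lte(res$pooled$se, min(ft$se))
  # hmp_raw between the extreme fold p-values; calibrated >= raw
  expect_gte(res$pooled$hmp_raw, min(ft$p))
  expect_lte(res$pooled$hmp_raw, max(ft$p))
  expect_gte(res$pooled$p_calibrated, res$pooled$hmp_raw)
  # quartile table: Q1 pinned at 1
  expect_equal(res$quartiles$hr[1], 1.0)
  expect_equal(nrow(res$quartiles), 4L)
  # out-of-fold scores all filled
  expect_false(anyNA(res$score))
})
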