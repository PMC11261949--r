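test_that("ground-truth labelling honours tissue thresholds and the BRCA OR-rule", {
  expect_equal(label_ground_truth(42, FALSE, "breast"), "HRD")
  expect_equal(label_ground_truth(41.99, FALSE, "breast"), "HRP")
  expect_equal(label_ground_truth(63, FALSE, "ovarian"), "HRD")
  expect_equal(label_ground_truth(62.9, FALSE, "ovarian"), "HRP")
  expect_equal(label_ground_truth(10, TRUE, "ovarian"), "HRD")
  expect_equal(label_ground_truth(NA, TRUE, "breast"), "HRD")
  # a breast-threshold score does not flip an ovarian sample
  expect_equal(label_ground_truth(50, FALSE, "ovarian"), "HRP")
  # missing score without BRCA evidence is an error, not HRP
  expect_error(label_ground_truth(NA, FALSE, "breast"), "cannot label")
  expect_error(label_ground_truth(c(42, NA), c(FALSE, NA), "breast"), "brca")
})

test_that("standardization is exact, reversible, and safe for constant features", {
  f <- tibble::tibble(sample_id = c("a", "b"),
                      loh_1_40mb = c(0, 2), del5_mh = c(1, 3),
                      het_3_9_10_40mb = c(0, 1), ncgt = c(0.1, 0.3),
                      nctg = c(0.2, 0.6), het_2_4_gt40mb = c(0.5, 0.7))
  sc <- feature_scaler(f)
  xs <- scale_features(f, sc)
  expect_equal(unname(xs[, "loh_1_40mb"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_true(all(abs(colMeans(xs)) < 1e-10))
  expect_equal(unname(apply(xs, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # round-trip inversion
  back <- sweep(sweep(xs, 2, sc$sd, "*"), 2, sc$mean, "+")
  expect_equal(unname(back[, "ncgt"]), f$ncgt, tolerance = 1e-12)
  # constant feature: sd falls back to 1, standardized values 0
  f$het_2_4_gt40mb <- 0.4
  expect_warning(sc2 <- feature_scaler(f), "constant")
  expect_equal(unname(scale_features(f, sc2)[, "het_2_4_gt40mb"]), c(0, 0))
})

test_that("a separable cohort trains to AUC 1 with the expected weight orientation", {
  fc <- simulate_feature_cohort(50, 50, seed = 7)
  # collapse to an effectively 1-D problem: only loh carries signal
  fc1 <- fc
  for (col in c("del5_mh", "het_3_9_10_40mb", "ncgt", "nctg", "het_2_4_gt40mb")) {
    fc1[[col]] <- withr::with_seed(1, runif(nrow(fc1)))
  }
  fc1$loh_1_40mb <- ifelse(fc1$label == "HRD", 1, -1)
  m <- hrd_train(fc1, setNames(fc1$label, fc1$sample_id), seed = 7)
  expect_equal(m$cv_auc, 1.0)
  expect_gt(feature_weights(m)[["loh_1_40mb"]], 0)
})

test_that("training recovers the planted weight directions with high CV AUC", {
  fc <- simulate_feature_cohort(100, 100, seed = 3)
  m <- hrd_train(fc, setNames(fc$label, fc$sample_id), seed = 5)
  w <- feature_weights(m)
  expect_gt(m$cv_auc, 0.95)
  expect_true(all(w[c("loh_1_40mb", "del5_mh", "het_3_9_10_40mb", "ncgt")] > 0))
  expect_true(all(w[c("nctg", "het_2_4_gt40mb")] < 0))
  # the invariant linking reported weights to per-fold weights
  expect_equal(unname(w), unname(colMeans(m$cv_weights)))
  expect_equal(nrow(m$cv_weights), 10)
})

test_that("label-permuted training yields chance-level CV AUC", {
  fc <- simulate_feature_cohort(50, 50, seed = 11)
  aucs <- withr::with_seed(19, {
    vapply(1:5, function(i) {
      perm <- setNames(sample(fc$label), fc$sample_id)
      hrd_train(fc, perm, c_grid = 1, seed = i)$cv_auc
    }, numeric(1))
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("training is deterministic given the seed", {
  fc <- simulate_feature_cohort(30, 30, seed = 2)
  m1 <- hrd_train(fc, setNames(fc$label, fc$sample_id), folds = 5, seed = 9)
  m2 <- hrd_train(fc, setNames(fc$label, fc$sample_id), folds = 5, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$cv_weights, m2$cv_weights)
  expect_identical(m1$calib_intercept, m2$calib_intercept)
})

test_that("prediction applies the inclusive 0.50 threshold and is monotone", {
  fc <- simulate_feature_cohort(40, 40, seed = 4)
  m <- hrd_train(fc, setNames(fc$label, fc$sample_id), folds = 5, seed = 1)
  p <- predict(m, fc)
  expect_true(all(p$call == ifelse(p$probability >= 0.5, "HRD", "HRP")))
  # monotone calibration: probability never decreases with decision value
  expect_true(all(diff(p$probability[order(p$decision_value)]) >= 0))
  expect_gt(cor(p$decision_value, p$probability), 0)
  # a sample sitting exactly on the threshold is called HRD (inclusive rule)
  expect_equal(unname(predict(m, fc, threshold = min(p$probability))$call[
    which.min(p$probability)]), "HRD")
  # missing feature column
  expect_error(predict(m, fc[, setdiff(names(fc), "ncgt")]), "ncgt")
})

test_that("calibration is sane: mean training probability near the HRD fraction", {
  fc <- simulate_feature_cohort(60, 40, seed = 8)
  m <- hrd_train(fc, setNames(fc$label, fc$sample_id), seed = 2)
  p <- predict(m, fc)
  expect_lt(abs(mean(p$probability) - 0.6), 0.1)
})

test_that("metrics match hand computation and the pairwise AUC oracle", {
  # perfect predictions
  perfect <- tibble::tibble(sample_id = letters[1:10],
                            probability = c(rep(0.9, 5), rep(0.1, 5)),
                            call = rep(c("HRD", "HRP"), each = 5))
  truth <- setNames(rep(c("HRD", "HRP"), each = 5), letters[1:10])
  met <- hrd_evaluate(perfect, truth)
  expect_equal(met$auc, 1)
  expect_equal(met$f1, 1)
  # all-tied probabilities give AUC 0.5
  tied <- dplyr::mutate(perfect, probability = 0.5)
  expect_equal(hrd_evaluate(tied, truth)$auc, 0.5)
  # random predictions vs the all-pairs concordance oracle
  withr::with_seed(23, {
    n <- 200
    scores <- sample(seq(0, 1, by = 0.05), n, TRUE)  # forces ties
    y <- sample(c(TRUE, FALSE), n, TRUE)
  })
  expect_equal(auc_rank(scores, y), oracle_auc(scores, y), tolerance = 1e-12)
  # undefined ratios are NA, not zero
  none_called <- dplyr::mutate(perfect, call = "HRP")
  met2 <- hrd_evaluate(none_called, truth)
  expect_true(is.na(met2$precision))
  expect_equal(met2$sensitivity, 0)
  expect_warning(
    hrd_evaluate(perfect[1:5, ], truth[1:5]), "one truth class")
})

test_that("models round-trip through JSON with identical predictions", {
  fc <- simulate_feature_cohort(30, 30, seed = 6)
  m <- hrd_train(fc, setNames(fc$label, fc$sample_id), folds = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict(m2, fc), predict(m, fc), tolerance = 1e-12)
  expect_equal(feature_weights(m2), feature_weights(m), tolerance = 1e-12)
  expect_equal(m2$cost, m$cost)
})

test_that("tidy and glance summarise models and metrics", {
  fc <- simulate_feature_cohort(30, 30, seed = 12)
  m <- hrd_train(fc, setNames(fc$label, fc$sample_id), folds = 5, seed = 3)
  td <- tidy(m)
  expect_equal(td$feature,
               c("loh_1_40mb", "del5_mh", "het_3_9_10_40mb", "ncgt", "nctg",
                 "het_2_4_gt40mb"))
  expect_equal(td$weight, unname(colMeans(m$cv_weights)))
  gl <- glance(m)
  expect_equal(gl$n_train, 60)
  met <- hrd_evaluate(predict(m, fc), setNames(fc$label, fc$sample_id))
  expect_named(glance(met), c("auc", "sensitivity", "precision", "f1", "n"))
  expect_equal(sum(tidy(met)$n), 60)
})
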