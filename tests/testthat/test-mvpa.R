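# Dataset assembly, scaling, classification, cross-validation, permutation.

assembled_fixture <- function(missed = NULL, seed = 31) {
  p <- small_protocol(n_day2_alt_runs = 0, n_day2_binary_runs = 0,
                      missed_blocks = missed)
  exp <- simulate_experiment(p, seed = seed)
  list(exp = exp,
       ds = assemble_dataset(quiet_preprocess(exp$day1),
                             feature_mask(exp$truth$brain_mask)))
}

test_that("fully acknowledged runs contribute 384 scans per class", {
  f <- assembled_fixture()
  expect_equal(sum(f$ds$y == 1), 384L)
  expect_equal(sum(f$ds$y == -1), 384L)
  # every block holds 16 scans of one class from one run
  expect_true(all(table(f$ds$block_id) == 16L))
})

test_that("a missed cue drops the block and its counterpart", {
  f <- assembled_fixture(missed = data.frame(run = 3, trial_type = "TASK_A",
                                             ordinal = 2))
  expect_equal(sum(f$ds$y == 1), 368L)
  expect_equal(sum(f$ds$y == -1), 368L)   # balance preserved
  # run 3 lost exactly one block pair (3 blocks per task, 16 scans each)
  expect_equal(sum(f$ds$run_id == 3), 3L * 16L * 2L - 32L)
})

test_that("min-max scaling maps training extremes to [-1, 1]", {
  tr <- matrix(c(2, 6, 1, 1), ncol = 2)   # second feature constant
  te <- matrix(c(4, 8, 1, 3), ncol = 2)
  sc <- minmax_scale(tr, te)
  expect_equal(sc$train[, 1], c(-1, 1))
  expect_equal(sc$other[, 1], c(0, 2))    # out-of-range values not clipped
  expect_equal(sc$train[, 2], c(0, 0))    # constant feature -> 0
  expect_equal(sc$other[, 2], c(0, 0))
})

test_that("the linear classifier agrees with a brute-force QP oracle", {
  # toy whose per-feature range is already [-1, 1]: scaling is the identity
  X <- rbind(c(1, 0.5), c(0.5, 1), c(-1, -0.5), c(-0.5, -1))
  y <- c(1, 1, -1, -1)
  ds <- structure(list(X = X, y = y, block_id = 1:4, run_id = rep(1L, 4),
                       mask_ref = list(voxels = 1:2, grid = c(2, 1, 1),
                                       kind = "WHOLE_BRAIN")),
                  class = "labeled_scan_set")
  model <- train_classifier(ds, svm_config(C = 1, tolerance = 1e-8))
  oracle <- smo_svm_oracle(X, y, C = 1)
  expect_equal(model$w, oracle$w, tolerance = 1e-4)
  expect_equal(model$b, oracle$b, tolerance = 1e-4)
  expect_equal(svm_primal_objective(model$w, model$b, X, y, 1),
               svm_primal_objective(oracle$w, oracle$b, X, y, 1),
               tolerance = 1e-4)
  # symmetric configuration: weight vector parallel to class-mean difference
  mdiff <- colMeans(X[y == 1, ]) - colMeans(X[y == -1, ])
  cosine <- sum(model$w * mdiff) / sqrt(sum(model$w^2) * sum(mdiff^2))
  expect_equal(cosine, 1, tolerance = 1e-6)

  # a two-point problem is classified with the right signs
  X2 <- matrix(c(1, -1), ncol = 1)
  ds2 <- ds; ds2$X <- X2; ds2$y <- c(1, -1); ds2$block_id <- 1:2
  m2 <- train_classifier(ds2)
  p2 <- predict_scans(m2, X2)
  expect_gt(p2$values[1], 0)
  expect_lt(p2$values[2], 0)

  ds_one_class <- ds2
  ds_one_class$y <- c(1, 1)
  expect_error(train_classifier(ds_one_class), "both classes")
})

test_that("flipping every label negates the decision function", {
  set.seed(33)
  X <- matrix(runif(40 * 3, -1, 1), 40, 3)
  X[1, ] <- c(-1, -1, -1); X[2, ] <- c(1, 1, 1)  # pin the feature ranges
  y <- ifelse(rowSums(X) > 0, 1, -1)
  mk <- function(yy) structure(list(X = X, y = yy, block_id = seq_along(yy),
                                    run_id = rep(1L, length(yy)),
                                    mask_ref = list(voxels = 1:3,
                                                    grid = c(3, 1, 1),
                                                    kind = "WHOLE_BRAIN")),
                               class = "labeled_scan_set")
  cfg <- svm_config(tolerance = 1e-8)
  m1 <- train_classifier(mk(y), cfg)
  m2 <- train_classifier(mk(-y), cfg)
  expect_equal(m1$w, -m2$w, tolerance = 1e-6)
  expect_equal(m1$b, -m2$b, tolerance = 1e-6)
})

test_that("leave-one-run-out pools accuracy over held-out scans", {
  f <- assembled_fixture()
  cv <- loro_cv(f$ds)
  expect_equal(nrow(cv$folds), 8L)
  expect_equal(sum(cv$folds$n), 768L)
  # pooled accuracy is the scan-count weighted mean of fold accuracies
  expect_equal(cv$pooled_accuracy,
               sum(cv$folds$accuracy * cv$folds$n) / sum(cv$folds$n))
  single_run <- scandecode:::subset_scan_set(f$ds, f$ds$run_id == 1)
  expect_error(loro_cv(single_run), "at least 2 runs")
})

test_that("a separable noiseless dataset cross-validates perfectly", {
  # 32 s rests let the 32 s HRF kernel tail clear each shifted block window,
  # so raw noiseless patterns are linearly separable
  p <- small_protocol(rest_seconds = 32, noise = no_noise(),
                      n_day2_alt_runs = 0, n_day2_binary_runs = 0)
  exp <- simulate_experiment(p, seed = 35)
  raw <- lapply(exp$day1, drop_dummy_scans)
  ds <- assemble_dataset(raw, feature_mask(exp$truth$brain_mask))
  expect_equal(loro_cv(ds)$pooled_accuracy, 1)
})

test_that("feature scaling is fitted on training folds only", {
  f <- assembled_fixture()
  ds <- f$ds
  test_run <- ds$run_id == 1
  model <- train_classifier(scandecode:::subset_scan_set(ds, !test_run))
  # corrupting held-out scans must not change any training artifact
  ds2 <- ds
  ds2$X[test_run, ] <- ds2$X[test_run, ] * 100
  model2 <- train_classifier(scandecode:::subset_scan_set(ds2, !test_run))
  expect_identical(model$scaler, model2$scaler)
  expect_identical(model$w, model2$w)
})

test_that("block permutations preserve run structure and balance", {
  f <- assembled_fixture()
  ds <- f$ds
  yp <- scandecode:::with_seed(7, scandecode:::permute_block_labels(ds))
  # per-run balance preserved
  for (r in unique(ds$run_id)) {
    expect_equal(sum(yp[ds$run_id == r] == 1),
                 sum(ds$y[ds$run_id == r] == 1))
  }
  # labels constant within blocks
  for (b in unique(ds$block_id)) {
    expect_equal(length(unique(yp[ds$block_id == b])), 1L)
  }
})

test_that("the permutation test is deterministic and properly bounded", {
  p <- small_protocol(n_day1_runs = 2, n_day2_alt_runs = 0,
                      n_day2_binary_runs = 1)
  exp <- simulate_experiment(p, seed = 37)
  d1 <- quiet_preprocess(exp$day1)
  d2 <- quiet_preprocess(exp$day2_binary)
  vox <- which(exp$truth$brain_mask)
  ds <- assemble_dataset(d1, feature_mask(exp$truth$brain_mask))
  ev <- scandecode:::response_scan_matrix(d2, vox, p$answer_key)

  r1 <- balanced_block_permutation_test(ds, ev$X, ev$y,
                                        n_permutations = 30, seed = 5)
  r2 <- balanced_block_permutation_test(ds, ev$X, ev$y,
                                        n_permutations = 30, seed = 5)
  expect_identical(r1$null_accuracies, r2$null_accuracies)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 31)
  expect_lte(r1$p_value, 1)

  # the identity block assignment reproduces the observed accuracy: a
  # "permutation" that keeps every block's label must score identically
  model <- train_classifier(ds)
  obs <- mean(predict_scans(model, ev$X)$labels == ev$y)
  expect_equal(r1$observed_accuracy, obs)

  expect_error(balanced_block_permutation_test(ds, ev$X, ev$y,
                                               n_permutations = 0), ">= 1")
})

test_that("day-1 classifiers transfer to day-2 alternating runs", {
  p <- small_protocol(n_day1_runs = 4, n_day2_alt_runs = 2,
                      n_day2_binary_runs = 0)
  exp <- simulate_experiment(p, seed = 39)
  wb <- feature_mask(exp$truth$brain_mask)
  ds1 <- assemble_dataset(quiet_preprocess(exp$day1), wb)
  ds2 <- assemble_dataset(quiet_preprocess(exp$day2_alt), wb)
  model <- train_classifier(ds1)
  acc2 <- mean(predict_scans(model, ds2$X)$labels == ds2$y)
  cv <- loro_cv(ds1)
  # same generative process on both days: cross-day accuracy within
  # sampling error of same-day cross-validation (binomial, n = 192)
  expect_lt(abs(acc2 - cv$pooled_accuracy), 3 * sqrt(0.25 / 192))
})
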