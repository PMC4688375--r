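# GLM contrasts and split-half feature selection.

test_that("the single-run design matrix has the documented columns", {
  sched <- build_alternating_run(acq_params())
  conf <- as.data.frame(matrix(rnorm(144 * 6), 144, 6,
                               dimnames = list(NULL,
                                               c("trans_x", "trans_y", "trans_z",
                                                 "rot_x", "rot_y", "rot_z"))))
  d <- build_design_matrix(list(sched), list(conf))
  # 2 task + 6 motion + 1 run constant + 4 DCT
  expect_equal(ncol(d$X), 13L)
  expect_equal(nrow(d$X), 144L)
  expect_equal(d$interest, 1:2)

  # convolved task regressor peaks at least 4 s after block onset
  x_a <- d$X[, 1]
  first_block_scans <- 1:30
  t_peak <- (which.max(x_a[first_block_scans]) - 1) * 2     # s after trim
  onset_trimmed <- 6 - 3 * 2                                 # block onset 6 s, 3 dummies
  expect_gte(t_peak - onset_trimmed, 4)
})

test_that("unacknowledged blocks only change their local regressor support", {
  sched <- build_alternating_run(acq_params())
  conf <- as.data.frame(matrix(0, 144, 6,
                               dimnames = list(NULL,
                                               c("trans_x", "trans_y", "trans_z",
                                                 "rot_x", "rot_y", "rot_z"))))
  d_full <- build_design_matrix(list(sched), list(conf))
  d_drop <- build_design_matrix(list(mark_unacknowledged(sched, "TASK_A", 2)),
                                list(conf))
  delta <- abs(d_full$X[, 1] - d_drop$X[, 1])
  changed <- which(delta > 1e-12)
  # support of block 2 (onset 102 s) convolved with a 32 s kernel:
  # scans inside [102, 102 + 32 + 32) s, minus the 6 s dummy lead-in
  lo <- (102 - 6) / 2; hi <- (102 + 64 - 6) / 2
  expect_true(all(changed - 1 >= lo & changed - 1 < hi))
  expect_equal(d_full$X[, 2], d_drop$X[, 2])   # other task untouched

  both_dropped <- mark_unacknowledged(
    mark_unacknowledged(mark_unacknowledged(sched, "TASK_A", 1),
                        "TASK_A", 2), "TASK_A", 3)
  expect_error(build_design_matrix(list(both_dropped), list(conf)),
               "degenerate")
})

test_that("fit_glm matches the closed-form OLS oracle", {
  set.seed(11)
  X <- cbind(1, matrix(rnorm(60), 30, 2))
  Y <- matrix(rnorm(30 * 5), 30, 5)
  fit <- fit_glm(Y, list(X = X), use_ar1 = FALSE)
  cvec <- c(0, 1, -1)
  tm <- contrast_tmap(fit, cvec)
  for (v in 1:5) {
    o <- ols_oracle(X, Y[, v], cvec)
    expect_equal(fit$beta[, v], o$beta, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$sigma2[[v]], o$sigma2, tolerance = 1e-8)
    expect_equal(tm$t[[v]], o$t, tolerance = 1e-8)
  }
  expect_equal(fit$dof, 27)

  # noiseless data are reproduced exactly
  b <- c(2, -1, 0.5)
  fitn <- fit_glm(X %*% b, list(X = X), use_ar1 = FALSE)
  expect_equal(as.numeric(fitn$beta), b, tolerance = 1e-8)
  expect_equal(fitn$sigma2[[1]], 0, tolerance = 1e-12)
})

test_that("the pooled AR(1) estimate recovers the simulated coefficient", {
  set.seed(12)
  n <- 5000
  Y <- sapply(1:20, function(v)
    as.numeric(stats::filter(rnorm(n), 0.4, method = "recursive")))
  fit <- fit_glm(Y, list(X = matrix(1, n, 1)), use_ar1 = TRUE)
  expect_equal(fit$rho, 0.4, tolerance = 0.05)
  expect_equal(fit$dof, n - 1 - 1)
})

test_that("contrast maps behave linearly", {
  set.seed(13)
  X <- cbind(1, matrix(rnorm(80), 40, 2))
  fit <- fit_glm(matrix(rnorm(40 * 6), 40, 6), list(X = X), use_ar1 = FALSE)
  expect_equal(contrast_tmap(fit, c(0, 0, 0))$t, rep(0, 6))
  expect_equal(contrast_tmap(fit, c(0, 1, -1))$t,
               -contrast_tmap(fit, c(0, -1, 1))$t)
  expect_error(contrast_tmap(fit, c(1, 0)), "length")
})

test_that("thresholding keeps voxels above the one-sided t cutoff", {
  grid <- c(5L, 5L, 2L)
  vox <- seq_len(50)
  tvals <- seq(-5, 5, length.out = 50)
  tm <- structure(list(t = tvals, contrast = c(1, -1), dof = 100),
                  class = "tmap")
  m <- threshold_mask(tm, "P001", 50, grid, vox)
  # inverse survival of t(100) at 0.001 is about 3.174
  expect_equal(m$t_cutoff, qt(0.999, 100), tolerance = 1e-10)
  expect_equal(m$n_voxels, sum(tvals > qt(0.999, 100)))

  # Bonferroni mask nested in the uncorrected mask when 0.05/n < 0.001
  mf <- threshold_mask(tm, "FWE05", 5000, grid, vox)
  expect_true(all(which(mf$mask) %in% which(m$mask)))

  # all-zero map selects nothing
  tm0 <- structure(list(t = rep(0, 50), contrast = c(1, -1), dof = 100),
                   class = "tmap")
  expect_equal(threshold_mask(tm0, "P001", 50, grid, vox)$n_voxels, 0L)

  # lowering the threshold level never adds voxels
  sizes <- sapply(c("P001", "FWE05"), function(k)
    threshold_mask(tm, k, 5000, grid, vox)$n_voxels)
  expect_lte(sizes["FWE05"], sizes["P001"])
})

test_that("opposite one-sided masks union disjointly and commute", {
  grid <- c(4L, 4L, 2L)
  m1 <- array(FALSE, grid); m1[1:2, , ] <- TRUE
  m2 <- array(FALSE, grid); m2[4, , ] <- TRUE
  fa <- feature_mask(m1, "P001"); fb <- feature_mask(m2, "P001")
  u <- union_contrast_masks(fa, fb)
  expect_equal(u$n_voxels, fa$n_voxels + fb$n_voxels)
  expect_equal(u$mask, union_contrast_masks(fb, fa)$mask)
  empty <- feature_mask(array(FALSE, grid), "P001")
  expect_equal(union_contrast_masks(fa, empty)$mask, fa$mask)
  expect_error(union_contrast_masks(fa, feature_mask(m2, "FWE05")),
               "threshold kinds")
})

test_that("split-half masks recover the planted pattern without leakage", {
  # high-CNR simulation: strong effect, little noise
  p <- small_protocol(n_day1_runs = 4, n_day2_alt_runs = 0,
                      n_day2_binary_runs = 0, beta_max = 0.08,
                      noise = noise_config(sigma = 0.005))
  exp <- simulate_experiment(p, seed = 21)
  masks <- split_half_masks(exp$day1)

  truth_diff <- abs(exp$truth$beta_a - exp$truth$beta_b)
  planted <- which(truth_diff > 0.2 * max(truth_diff) & exp$truth$brain_mask)
  for (half in c("odd", "even")) {
    recovery <- mean(planted %in% which(masks$P001[[half]]$mask))
    expect_gte(recovery, 0.8)
  }

  # no leakage: corrupting the even runs cannot change the odd-run mask
  exp2 <- exp
  for (i in c(2, 4)) exp2$day1[[i]]$data <- exp2$day1[[i]]$data * 0 +
    rnorm(length(exp2$day1[[i]]$data))
  masks2 <- split_half_masks(exp2$day1)
  expect_identical(masks$P001$odd$mask, masks2$P001$odd$mask)
  expect_identical(masks$FWE05$odd$mask, masks2$FWE05$odd$mask)
  expect_false(identical(masks$P001$even$mask, masks2$P001$even$mask))

  expect_error(split_half_masks(exp$day1[1:3]), "even number")
})
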