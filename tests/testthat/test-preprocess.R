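# Voxelwise clean-up chain.

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(1)
  g <- c(4L, 4L, 2L)
  mask <- all_true_mask(g)
  M <- matrix(rnorm(20 * prod(g), mean = 100), 20, prod(g))
  run <- make_matrix_run(M, mask)

  # a voxel equal to a confound column residualizes to zero
  M2 <- M
  M2[, 1] <- run$confounds$c2
  run2 <- make_matrix_run(M2, mask, confounds = run$confounds)
  out <- regress_nuisance(run2)
  expect_lt(max(abs(scandecode:::run_matrix(out)[, 1])), 1e-10)

  # orthogonality on random data
  out <- regress_nuisance(run)
  R <- scandecode:::run_matrix(out)
  X <- cbind(1, as.matrix(run$confounds))
  expect_lt(max(abs(t(R) %*% X)), 1e-8)
})

test_that("nuisance regression matches the explicit projection matrix", {
  set.seed(2)
  g <- c(3L, 3L, 2L)
  mask <- all_true_mask(g)
  M <- matrix(rnorm(20 * prod(g)), 20, prod(g))
  run <- make_matrix_run(M, mask)
  X <- cbind(1, as.matrix(run$confounds))
  expect_equal(scandecode:::run_matrix(regress_nuisance(run)),
               projection_oracle(X, M), tolerance = 1e-10)
})

test_that("rank-deficient nuisance matrices are handled with a warning", {
  set.seed(3)
  g <- c(3L, 3L, 2L)
  conf <- data.frame(c1 = rnorm(15))
  conf$c2 <- 2 * conf$c1   # exactly collinear
  run <- make_matrix_run(matrix(rnorm(15 * 18), 15, 18), all_true_mask(g),
                         confounds = conf)
  expect_warning(out <- regress_nuisance(run), "rank deficient")
  R <- scandecode:::run_matrix(out)
  expect_lt(max(abs(t(R) %*% cbind(1, as.matrix(conf)))), 1e-8)
})

test_that("the DCT high-pass removes exactly the sub-cutoff band", {
  # 288 s of data: 4 components fall below both study cutoffs
  expect_equal(ncol(dct_highpass_basis(144, 2, 0.008)), 4L)
  expect_equal(ncol(dct_highpass_basis(144, 2, 0.0078)), 4L)

  g <- c(3L, 3L, 2L)
  mask <- all_true_mask(g)
  B <- dct_highpass_basis(144, 2, 0.008)

  # an in-basis slow cosine is annihilated
  M <- matrix(rep(B[, 1], prod(g)), 144, prod(g))
  run <- highpass_dct(make_matrix_run(M + 5, mask), 0.008)
  expect_lt(max(abs(scandecode:::run_matrix(run) - 5)) /
              max(abs(B[, 1])), 1e-8)

  # a far-above-cutoff component of the same cosine family is exactly
  # orthogonal to the removed set and passes unchanged (a raw +1/-1
  # alternation is NOT invariant: it has O(1/n) overlap with every odd
  # slow DCT column, so only in-family high frequencies are preserved
  # exactly)
  Bfull <- sapply(c(40, 71), function(j)
    cos(pi * (2 * (0:143) + 1) * j / (2 * 144)))
  hi <- Bfull[, 1] + 0.5 * Bfull[, 2]   # 0.14 and 0.25 Hz content
  M <- matrix(rep(hi, prod(g)), 144, prod(g))
  run <- highpass_dct(make_matrix_run(M, mask), 0.008)
  expect_equal(scandecode:::run_matrix(run)[, 1], hi, tolerance = 1e-10)

  expect_error(highpass_dct(make_matrix_run(M, mask), 0.3), "Nyquist")
})

test_that("grand-mean scaling is a pure rescaling to the target", {
  set.seed(4)
  g <- c(4L, 4L, 2L)
  mask <- all_true_mask(g)
  M <- matrix(runif(30 * prod(g), 150, 250), 30, prod(g))
  run <- grand_mean_scale(make_matrix_run(M, mask), 100)
  S <- scandecode:::run_matrix(run)
  expect_equal(mean(S), 100, tolerance = 1e-8)
  # halving: grand mean 200 -> all values halved
  expect_equal(S, M * (100 / mean(M)), tolerance = 1e-10)
  # voxel ratios preserved
  expect_equal(S[, 1] / S[, 2], M[, 1] / M[, 2], tolerance = 1e-10)
  expect_error(grand_mean_scale(make_matrix_run(M - 500, mask)), "positive")
})

test_that("day-level standardization pools statistics across runs", {
  g <- c(3L, 3L, 2L)
  mask <- all_true_mask(g)
  # constant within run, different between runs: day pooling must keep the
  # between-run difference as signal
  M1 <- matrix(10, 20, prod(g)); M2 <- matrix(30, 20, prod(g))
  out <- standardize_day(list(make_matrix_run(M1, mask),
                              make_matrix_run(M2, mask)))
  s1 <- scandecode:::run_matrix(out[[1]])
  expect_true(all(abs(s1) > 0.5))

  # day-level mean 0 / SD 1 on random data
  set.seed(5)
  M1 <- matrix(rnorm(20 * prod(g), 100, 5), 20, prod(g))
  M2 <- matrix(rnorm(25 * prod(g), 100, 5), 25, prod(g))
  out <- standardize_day(list(make_matrix_run(M1, mask),
                              make_matrix_run(M2, mask)))
  cat_series <- rbind(scandecode:::run_matrix(out[[1]]),
                      scandecode:::run_matrix(out[[2]]))
  expect_equal(colMeans(cat_series), rep(0, prod(g)), tolerance = 1e-8)
  expect_equal(apply(cat_series, 2, sd), rep(1, prod(g)), tolerance = 1e-8)

  # single run degenerates to per-run z-scoring
  out1 <- standardize_day(list(make_matrix_run(M1, mask)))
  expect_equal(scandecode:::run_matrix(out1[[1]]), scale(M1),
               tolerance = 1e-10, ignore_attr = TRUE)

  # standardizing twice changes nothing
  out2 <- standardize_day(out)
  expect_equal(scandecode:::run_matrix(out2[[1]]),
               scandecode:::run_matrix(out[[1]]), tolerance = 1e-8)

  # zero-variance voxels are zeroed with a warning
  Mc <- M1; Mc[, 3] <- 7
  expect_warning(outc <- standardize_day(list(make_matrix_run(Mc, mask))),
                 "zero-variance")
  expect_equal(scandecode:::run_matrix(outc[[1]])[, 3], rep(0, 20))
})

test_that("gaussian smoothing matches a direct convolution oracle", {
  g <- c(7L, 7L, 5L)
  vol <- array(0, g); vol[4, 4, 3] <- 1
  expect_identical(gaussian_smooth(vol, 0, c(3, 3, 5)), vol)
  expect_equal(gaussian_smooth(vol, 8, c(3, 3, 5)),
               direct_gaussian_conv3d(vol, 8, c(3, 3, 5)),
               tolerance = 1e-8)

  # mass is conserved when the kernel support stays inside the volume
  # (zero padding loses mass only at the edges)
  g2 <- c(11L, 11L, 11L)
  vol2 <- array(0, g2); vol2[6, 6, 6] <- 1
  sm <- gaussian_smooth(vol2, 8, c(3, 3, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(sm, direct_gaussian_conv3d(vol2, 8, c(3, 3, 3)),
               tolerance = 1e-8)

  set.seed(6)
  vol <- array(rnorm(prod(g)), g)
  expect_equal(gaussian_smooth(vol, 6, c(3, 3, 5)),
               direct_gaussian_conv3d(vol, 6, c(3, 3, 5)),
               tolerance = 1e-8)
})

test_that("all chain operations leave out-of-mask voxels untouched", {
  set.seed(7)
  g <- c(4L, 4L, 2L)
  mask <- array(FALSE, g); mask[2:3, 2:3, ] <- TRUE
  M <- matrix(rnorm(20 * prod(g), 100), 20, prod(g))
  run0 <- make_matrix_run(M, mask)
  out_vox <- which(!mask)
  for (op in list(regress_nuisance,
                  function(r) highpass_dct(r, 0.01),
                  function(r) grand_mean_scale(r, 100),
                  function(r) standardize_day(list(r))[[1]])) {
    out <- op(run0)
    expect_equal(scandecode:::run_matrix(out)[, out_vox], M[, out_vox])
  }
})

test_that("the chain runs in the documented order and records it", {
  exp <- simulate_experiment(small_protocol(n_day1_runs = 2,
                                            n_day2_alt_runs = 0,
                                            n_day2_binary_runs = 0),
                             seed = 9)
  pre <- quiet_preprocess(exp$day1)
  steps <- pre[[1]]$provenance$steps
  expect_equal(steps[steps != "simulate"],
               c("drop_dummy_scans", "regress_nuisance",
                 "highpass_dct(0.008)", "restore_session_mean",
                 "grand_mean_scale(100)", "standardize_day"))
  # dummy scans are gone
  expect_equal(dim(pre[[1]]$data)[4], 144L)
})
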