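# Voxelwise clean-up chain applied before pattern classification, plus
# Gaussian smoothing for the univariate GLM branch.
#
# The multivariate branch runs, in order: nuisance regression (confounds +
# per-session constant) -> discrete-cosine high-pass at 0.008 Hz ->
# per-session grand-mean scaling to 100 -> day-level voxelwise
# standardization pooled across the day's runs. Because residualization
# removes the session mean, the session-mean image is added back before
# grand-mean scaling so that a zero-mean series is never scaled.
# All operations respect the brain mask: out-of-mask voxels are untouched.

#' Preprocessing configuration
#'
#' @param hp_cutoff_hz high-pass cutoff in Hz (default 0.008).
#' @param grand_mean_target target grand mean (default 100).
#' @param smooth_fwhm_mm Gaussian smoothing FWHM in mm for the GLM branch
#'   (default 8; the multivariate branch is never smoothed).
#' @return Object of class `preproc_config`.
#' @export
preproc_config <- function(hp_cutoff_hz = 0.008, grand_mean_target = 100,
                           smooth_fwhm_mm = 8) {
  if (hp_cutoff_hz <= 0) stop_config("hp_cutoff_hz must be positive")
  if (grand_mean_target <= 0) stop_config("grand_mean_target must be positive")
  if (smooth_fwhm_mm < 0) stop_config("smooth_fwhm_mm must be non-negative")
  structure(list(hp_cutoff_hz = hp_cutoff_hz,
                 grand_mean_target = grand_mean_target,
                 smooth_fwhm_mm = smooth_fwhm_mm),
            class = "preproc_config")
}

#' Drop lead-in (dummy) scans from a run
#'
#' Removes the first `n_dummy_scans` volumes and confound rows. Idempotent:
#' a run whose dummies were already dropped is returned unchanged.
#'
#' @param run a `bold_run`.
#' @return The trimmed `bold_run`, with `n_dummy_dropped` recording the
#'   offset between schedule scan indices and data volumes.
#' @export
drop_dummy_scans <- function(run) {
  nd <- run$schedule$acquisition$n_dummy_scans
  if (run$n_dummy_dropped > 0 || nd == 0) return(run)
  run$data <- run$data[, , , -(seq_len(nd)), drop = FALSE]
  run$confounds <- run$confounds[-(seq_len(nd)), , drop = FALSE]
  rownames(run$confounds) <- NULL
  run$n_dummy_dropped <- as.integer(nd)
  run$provenance$steps <- c(run$provenance$steps, "drop_dummy_scans")
  run
}

n_kept_scans <- function(run) dim(run$data)[4]

add_step <- function(run, step) {
  run$provenance$steps <- c(run$provenance$steps, step)
  run
}

#' Regress nuisance variables from every in-mask voxel
#'
#' Replaces each voxel's time series by its ordinary-least-squares residual
#' against the run's confound columns plus a session constant. Residuals
#' are orthogonal to every regressor column. A rank-deficient regressor
#' matrix is handled on its column space with a warning.
#'
#' @param run a `bold_run`.
#' @param extra_regressors optional additional per-scan regressor matrix.
#' @return The residualized `bold_run`.
#' @export
regress_nuisance <- function(run, extra_regressors = NULL) {
  X <- cbind(session_constant = 1, as.matrix(run$confounds))
  if (!is.null(extra_regressors)) X <- cbind(X, extra_regressors)
  if (nrow(X) != n_kept_scans(run))
    stop_config("regressor rows must equal the number of scans")
  M <- run_matrix(run)
  vox <- which(run$brain_mask)
  M[, vox] <- residualize(M[, vox, drop = FALSE], X)
  run <- set_run_matrix(run, M)
  add_step(run, "regress_nuisance")
}

#' Discrete-cosine high-pass basis
#'
#' DCT-II columns `cos(pi * (2t + 1) * j / (2n))` for all `j >= 1` whose
#' frequency `j / (2 * D)` lies strictly below the cutoff, where `D` is the
#' run duration in seconds.
#'
#' @param n_scans number of scans.
#' @param tr repetition time in seconds.
#' @param cutoff_hz cutoff frequency.
#' @return Matrix with `n_scans` rows (zero columns when nothing falls
#'   below the cutoff).
#' @export
dct_highpass_basis <- function(n_scans, tr, cutoff_hz) {
  D <- n_scans * tr
  K <- floor(2 * D * cutoff_hz - 1e-9)
  t0 <- seq_len(n_scans) - 1
  B <- matrix(0, n_scans, max(K, 0))
  for (j in seq_len(max(K, 0)))
    B[, j] <- cos(pi * (2 * t0 + 1) * j / (2 * n_scans))
  B
}

#' High-pass filter a run by DCT residualization
#'
#' Removes the discrete-cosine components below `cutoff_hz` from every
#' in-mask voxel (the SPM-style high-pass). The cutoff must lie below the
#' Nyquist frequency `1 / (2 * TR)`.
#'
#' @param run a `bold_run`.
#' @param cutoff_hz cutoff frequency in Hz.
#' @return The filtered `bold_run`.
#' @export
highpass_dct <- function(run, cutoff_hz = 0.008) {
  tr <- run$schedule$acquisition$tr_seconds
  if (cutoff_hz >= 1 / (2 * tr))
    stop_config("cutoff must be below the Nyquist frequency")
  n <- n_kept_scans(run)
  B <- dct_highpass_basis(n, tr, cutoff_hz)
  if (ncol(B) == 0) return(add_step(run, "highpass_dct(noop)"))
  M <- run_matrix(run)
  vox <- which(run$brain_mask)
  M[, vox] <- residualize(M[, vox, drop = FALSE], B, warn_rank = FALSE)
  run <- set_run_matrix(run, M)
  add_step(run, sprintf("highpass_dct(%g)", cutoff_hz))
}

#' Scale a run to a target grand mean
#'
#' Multiplies the in-mask data so that the mean over all in-mask voxels and
#' scans equals `target`. Purely multiplicative: voxel ratios are preserved.
#'
#' @param run a `bold_run`.
#' @param target target grand mean (default 100).
#' @return The rescaled `bold_run`.
#' @export
grand_mean_scale <- function(run, target = 100) {
  M <- run_matrix(run)
  vox <- which(run$brain_mask)
  gm <- mean(M[, vox])
  if (!is.finite(gm) || gm <= 0)
    stop_config("grand mean must be positive before scaling (got ",
                format(gm), ")")
  M[, vox] <- M[, vox] * (target / gm)
  run <- set_run_matrix(run, M)
  add_step(run, sprintf("grand_mean_scale(%g)", target))
}

#' Standardize voxels over a day
#'
#' Z-scores each in-mask voxel using its mean and SD pooled over the
#' concatenated time series of all the day's runs (not per run, so stable
#' between-run differences survive as signal). Voxels with zero pooled
#' variance are set to zero with a warning.
#'
#' @param runs list of `bold_run` belonging to one day.
#' @return The list of standardized runs.
#' @export
standardize_day <- function(runs) {
  stopifnot(length(runs) >= 1)
  vox <- which(runs[[1]]$brain_mask)
  mats <- lapply(runs, function(r) run_matrix(r)[, vox, drop = FALSE])
  all_t <- do.call(rbind, mats)
  mu <- colMeans(all_t)
  sdv <- apply(all_t, 2, stats::sd)
  # a voxel is flat when its SD is zero up to float rounding of its own
  # magnitude; exact comparison would let accumulated arithmetic residue
  # (~1e-13 of the signal level) be inflated to unit variance
  flat <- !is.finite(sdv) | sdv <= 1e-9 * pmax(abs(mu), 1)
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel(s) set to zero", call. = FALSE)
    sdv[flat] <- 1
    mu[flat] <- 0
  }
  lapply(seq_along(runs), function(i) {
    M <- run_matrix(runs[[i]])
    Z <- sweep(sweep(mats[[i]], 2, mu), 2, sdv, "/")
    Z[, flat] <- 0
    M[, vox] <- Z
    add_step(set_run_matrix(runs[[i]], M), "standardize_day")
  })
}

gaussian_kernel_1d <- function(sd_vox) {
  if (sd_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sd_vox))
  k <- stats::dnorm(seq(-r, r), sd = sd_vox)
  k / sum(k)
}

conv1d_zero <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(x * k)
  xp <- c(numeric(r), x, numeric(r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths a 3D volume with a separable Gaussian of the given full width at
#' half maximum; per-axis SD in voxels is
#' `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`. Volume edges are
#' constant-(zero-)padded. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(volume)) == 3, length(voxel_size_mm) == 3)
  if (fwhm_mm < 0) stop_config("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(volume)
  sds <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- volume
  k <- gaussian_kernel_1d(sds[1])
  out <- apply(out, c(2, 3), conv1d_zero, k = k)
  k <- gaussian_kernel_1d(sds[2])
  out <- aperm(apply(out, c(1, 3), conv1d_zero, k = k), c(2, 1, 3))
  k <- gaussian_kernel_1d(sds[3])
  out <- aperm(apply(out, c(1, 2), conv1d_zero, k = k), c(2, 3, 1))
  dim(out) <- dim(volume)
  out
}

#' Smooth every volume of a run (GLM branch)
#'
#' @param run a `bold_run`.
#' @param fwhm_mm smoothing FWHM in mm.
#' @return The smoothed `bold_run`.
#' @export
smooth_run <- function(run, fwhm_mm = 8) {
  if (fwhm_mm == 0) return(run)
  vs <- run$schedule$acquisition$voxel_size_mm
  for (t in seq_len(dim(run$data)[4]))
    run$data[, , , t] <- gaussian_smooth(run$data[, , , t], fwhm_mm, vs)
  add_step(run, sprintf("smooth(%gmm)", fwhm_mm))
}

#' Run the multivariate-branch preprocessing chain on one day's runs
#'
#' For each run: drop dummy scans, regress nuisance variables (confounds +
#' session constant), DCT high-pass, restore the session-mean image,
#' grand-mean scale to the target; finally standardize voxelwise across the
#' whole day. The step order is recorded in each run's provenance.
#'
#' @param runs list of `bold_run` acquired on one day.
#' @param config a [preproc_config()].
#' @return List of preprocessed runs.
#' @export
preprocess_day <- function(runs, config = preproc_config()) {
  runs <- lapply(runs, function(run) {
    run <- drop_dummy_scans(run)
    vox <- which(run$brain_mask)
    mean_img <- colMeans(run_matrix(run)[, vox, drop = FALSE])
    run <- regress_nuisance(run)
    run <- highpass_dct(run, config$hp_cutoff_hz)
    M <- run_matrix(run)
    M[, vox] <- sweep(M[, vox, drop = FALSE], 2, mean_img, "+")
    run <- add_step(set_run_matrix(run, M), "restore_session_mean")
    grand_mean_scale(run, config$grand_mean_target)
  })
  standardize_day(runs)
}
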