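# Univariate GLM on smoothed data, task contrasts, thresholding, and
# split-half feature-mask generation.
#
# The GLM branch shares only the raw runs with the multivariate branch: it
# operates on spatially smoothed, unstandardized data, with motion, per-run
# constants and a per-run DCT high-pass set (0.0078 Hz) inside the design
# matrix rather than removed beforehand.

#' GLM configuration
#'
#' @param hp_cutoff_hz high-pass cutoff used inside the design (default
#'   0.0078; the multivariate branch uses 0.008 — both defaults are kept
#'   distinct deliberately).
#' @param use_ar1 prewhiten with a pooled AR(1) model (default TRUE).
#' @param boxcar_seconds task-block boxcar duration (default 32).
#' @return Object of class `glm_config`.
#' @export
glm_config <- function(hp_cutoff_hz = 0.0078, use_ar1 = TRUE,
                       boxcar_seconds = 32) {
  structure(list(hp_cutoff_hz = hp_cutoff_hz, use_ar1 = use_ar1,
                 boxcar_seconds = boxcar_seconds), class = "glm_config")
}

#' Build the multi-run GLM design matrix
#'
#' Columns are: the TASK_A and TASK_B boxcars (acknowledged blocks only,
#' `boxcar_seconds` long, positioned at block onsets and convolved with the
#' canonical HRF), the six head-motion parameters, one constant per run,
#' and each run's DCT high-pass set. Rows are the dummy-stripped scans of
#' all runs concatenated in order. For one run with the default timing this
#' is 2 + 6 + 1 + 4 = 13 columns.
#'
#' @param schedules list of ALTERNATING `run_schedule`s.
#' @param confounds list of per-run confound tables (motion columns used),
#'   one row per retained scan.
#' @param cfg a [glm_config()].
#' @return List with `X` (design matrix), `run_index` (row -> run),
#'   `interest` (indices of the two task columns), `colnames`.
#' @export
build_design_matrix <- function(schedules, confounds, cfg = glm_config()) {
  stopifnot(length(schedules) == length(confounds))
  n_ack <- c(TASK_A = 0L, TASK_B = 0L)
  per_run <- lapply(seq_along(schedules), function(r) {
    s <- schedules[[r]]
    tr <- s$acquisition$tr_seconds
    nd <- s$acquisition$n_dummy_scans
    keep <- seq_len(s$n_scans) > nd
    ev <- s$events
    reg <- sapply(c("TASK_A", "TASK_B"), function(lab) {
      blk <- ev[ev$trial_type == lab & ev$acknowledged, , drop = FALSE]
      n_ack[lab] <<- n_ack[lab] + nrow(blk)
      convolved_regressor(blk$onset, rep(cfg$boxcar_seconds, nrow(blk)),
                          s$n_scans, tr)[keep]
    })
    n <- sum(keep)
    dct <- dct_highpass_basis(n, tr, cfg$hp_cutoff_hz)
    motion <- as.matrix(confounds[[r]][, c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z")])
    if (nrow(motion) != n)
      stop_config("confound rows must match retained scans")
    list(reg = reg, motion = motion, dct = dct, n = n)
  })
  if (any(n_ack == 0))
    stop_config("a task condition has no acknowledged blocks; ",
                "the design is degenerate")
  R <- length(per_run)
  n_tot <- sum(vapply(per_run, `[[`, 0, "n"))
  interest <- do.call(rbind, lapply(per_run, `[[`, "reg"))
  motion <- do.call(rbind, lapply(per_run, `[[`, "motion"))
  consts <- matrix(0, n_tot, R)
  n_dct <- vapply(per_run, function(p) ncol(p$dct), 0L)
  dct <- matrix(0, n_tot, sum(n_dct))
  run_index <- integer(n_tot)
  row0 <- 0L; col0 <- 0L
  for (r in seq_len(R)) {
    rows <- row0 + seq_len(per_run[[r]]$n)
    consts[rows, r] <- 1
    if (n_dct[r] > 0)
      dct[rows, col0 + seq_len(n_dct[r])] <- per_run[[r]]$dct
    run_index[rows] <- r
    row0 <- row0 + per_run[[r]]$n
    col0 <- col0 + n_dct[r]
  }
  X <- cbind(interest, motion, consts, dct)
  colnames(X) <- c("task_a", "task_b",
                   "trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z",
                   paste0("run", seq_len(R)),
                   unlist(lapply(seq_len(R), function(r)
                     if (n_dct[r] > 0) paste0("run", r, "_dct", seq_len(n_dct[r]))
                     else character(0))))
  list(X = X, run_index = run_index, interest = 1:2,
       colnames = colnames(X))
}

# pooled lag-1 autocorrelation of residual columns, lags taken within runs
pooled_lag1 <- function(R, run_index) {
  num <- 0; den <- 0
  for (r in unique(run_index)) {
    Rr <- R[run_index == r, , drop = FALSE]
    n <- nrow(Rr)
    num <- num + sum(Rr[-1, ] * Rr[-n, ])
    den <- den + sum(Rr^2)
  }
  max(min(num / den, 0.99), -0.99)
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares per voxel; with `use_ar1`, a single pooled AR(1)
#' coefficient is estimated from the lag-1 autocorrelation of the OLS
#' residuals (lags taken within runs), both data and design are prewhitened
#' by the AR(1) differencing transform (each run loses its first row), and
#' the model is refit. Degrees of freedom are the retained rows minus the
#' design rank.
#'
#' @param Y scans x voxels data matrix (runs concatenated).
#' @param design result of [build_design_matrix()], or a list with `X` and
#'   `run_index`.
#' @param use_ar1 logical; overrides per-call whether to prewhiten.
#' @return Object of class `glm_fit` with `beta` (coefficients x voxels),
#'   `sigma2`, `dof`, `rho`, `XtXinv`, `design_cols`.
#' @export
fit_glm <- function(Y, design, use_ar1 = TRUE) {
  X <- design$X
  run_index <- design$run_index %||% rep(1L, nrow(X))
  if (nrow(Y) != nrow(X))
    stop_config("data rows must equal design rows")
  if (nrow(X) < ncol(X))
    stop_config("design has fewer rows than columns")
  ols <- function(Xw, Yw) {
    qx <- qr(Xw)
    beta <- qr.coef(qx, Yw)
    beta[is.na(beta)] <- 0
    res <- Yw - Xw %*% beta
    list(qx = qx, beta = beta, res = res)
  }
  f <- ols(X, Y)
  rho <- 0
  if (use_ar1) {
    rho <- pooled_lag1(f$res, run_index)
    firsts <- !duplicated(run_index)
    Xw <- (X - rbind(0, X[-nrow(X), , drop = FALSE]) * rho)[!firsts, , drop = FALSE]
    Yw <- (Y - rbind(0, Y[-nrow(Y), , drop = FALSE]) * rho)[!firsts, , drop = FALSE]
    f <- ols(Xw, Yw)
    dof <- nrow(Xw) - f$qx$rank
  } else {
    dof <- nrow(X) - f$qx$rank
  }
  sigma2 <- colSums(f$res^2) / dof
  R <- qr.R(f$qx)
  XtXinv <- chol2inv(R)[order(f$qx$pivot), order(f$qx$pivot), drop = FALSE]
  structure(list(beta = f$beta, sigma2 = sigma2, dof = dof, rho = rho,
                 XtXinv = XtXinv, design_cols = colnames(X)),
            class = "glm_fit")
}

#' Contrast t-map
#'
#' `t(v) = c'beta(v) / sqrt(sigma2(v) * c' (X'X)^-1 c)` using the
#' (prewhitened) design. Voxels with zero residual variance and zero
#' contrast value get t = 0.
#'
#' @param fit a [fit_glm()] result.
#' @param cvec contrast vector of length `nrow(fit$beta)`.
#' @return Object of class `tmap` with `t` (per-voxel values), `contrast`,
#'   `dof`.
#' @export
contrast_tmap <- function(fit, cvec) {
  if (length(cvec) != nrow(fit$beta))
    stop_config("contrast length must match number of coefficients")
  num <- as.numeric(crossprod(cvec, fit$beta))
  varc <- as.numeric(crossprod(cvec, fit$XtXinv %*% cvec))
  se <- sqrt(fit$sigma2 * varc)
  t <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
  structure(list(t = t, contrast = cvec, dof = fit$dof), class = "tmap")
}

#' Threshold a t-map into a feature mask
#'
#' `P001` keeps voxels with one-sided p < 0.001 under Student-t(dof);
#' `FWE05` controls the family-wise error with a Bonferroni correction,
#' one-sided p < 0.05 / `n_voxels_tested`. Voxels strictly above the cutoff
#' are kept.
#'
#' @param tmap a [contrast_tmap()] result.
#' @param kind `"P001"` or `"FWE05"`.
#' @param n_voxels_tested number of voxels in the search volume.
#' @param grid 3 integers, the volume dimensions.
#' @param voxel_idx linear indices (into the grid) of the tested voxels,
#'   in the order of `tmap$t`.
#' @return Object of class `feature_mask`.
#' @export
threshold_mask <- function(tmap, kind = c("P001", "FWE05"), n_voxels_tested,
                           grid, voxel_idx) {
  kind <- match.arg(kind)
  if (tmap$dof <= 0) stop_config("degrees of freedom must be positive")
  alpha <- if (kind == "P001") 0.001 else 0.05 / n_voxels_tested
  cutoff <- stats::qt(1 - alpha, df = tmap$dof)
  keep <- tmap$t > cutoff
  mask <- array(FALSE, dim = grid)
  mask[voxel_idx[keep]] <- TRUE
  feature_mask(mask, kind, t_cutoff = cutoff, dof = tmap$dof)
}

#' Feature mask constructor
#'
#' @param mask logical 3D array of selected voxels.
#' @param threshold_kind `"P001"`, `"FWE05"`, or `"WHOLE_BRAIN"`.
#' @param source_runs run ids the mask was fitted on.
#' @param t_cutoff,dof threshold metadata (NA for whole-brain masks).
#' @return Object of class `feature_mask` with `n_voxels` filled in.
#' @export
feature_mask <- function(mask, threshold_kind = "WHOLE_BRAIN",
                         source_runs = integer(), t_cutoff = NA_real_,
                         dof = NA_real_) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(mask = mask, threshold_kind = threshold_kind,
                 source_runs = as.integer(source_runs),
                 n_voxels = sum(mask), t_cutoff = t_cutoff, dof = dof),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %s: %d voxels on %s grid\n", x$threshold_kind,
              x$n_voxels, paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Union of two one-sided contrast masks
#'
#' Voxelwise OR. The two one-sided masks from opposite contrasts at the
#' same threshold are disjoint, so the union size is the sum of sizes.
#'
#' @param mask_ab,mask_ba `feature_mask` objects on the same grid with the
#'   same `threshold_kind`.
#' @return The union `feature_mask`.
#' @export
union_contrast_masks <- function(mask_ab, mask_ba) {
  if (!identical(dim(mask_ab$mask), dim(mask_ba$mask)))
    stop_config("masks are on different grids")
  if (!identical(mask_ab$threshold_kind, mask_ba$threshold_kind))
    stop_config("masks have different threshold kinds")
  feature_mask(mask_ab$mask | mask_ba$mask, mask_ab$threshold_kind,
               source_runs = union(mask_ab$source_runs, mask_ba$source_runs),
               t_cutoff = mask_ab$t_cutoff, dof = mask_ab$dof)
}

#' GLM feature masks from a set of runs
#'
#' Smooths the raw runs, strips dummy scans, fits the multi-run GLM on all
#' in-mask voxels, computes both directed task contrasts
#' (TASK_A > TASK_B and TASK_B > TASK_A), thresholds each one-sided at both
#' levels, and unions the two directions per level.
#'
#' @param runs list of raw (unsmoothed, untrimmed) ALTERNATING `bold_run`s.
#' @param cfg a [glm_config()].
#' @param smooth_fwhm_mm smoothing applied before fitting (default 8).
#' @return List with `P001` and `FWE05` `feature_mask`s plus the `fit` and
#'   both `tmaps`.
#' @export
glm_select_masks <- function(runs, cfg = glm_config(), smooth_fwhm_mm = 8) {
  brain <- runs[[1]]$brain_mask
  grid <- dim(brain)
  vox <- which(brain)
  runs_s <- lapply(runs, function(r)
    drop_dummy_scans(smooth_run(r, smooth_fwhm_mm)))
  Y <- do.call(rbind, lapply(runs_s, function(r)
    run_matrix(r)[, vox, drop = FALSE]))
  design <- build_design_matrix(lapply(runs, function(r) r$schedule),
                                lapply(runs_s, function(r) r$confounds),
                                cfg)
  fit <- fit_glm(Y, design, use_ar1 = cfg$use_ar1)
  cvec <- numeric(ncol(design$X))
  cvec[design$interest] <- c(1, -1)
  t_ab <- contrast_tmap(fit, cvec)
  t_ba <- contrast_tmap(fit, -cvec)
  run_ids <- vapply(runs, function(r) r$schedule$run_id, 0L)
  one <- function(kind) {
    m <- union_contrast_masks(
      threshold_mask(t_ab, kind, length(vox), grid, vox),
      threshold_mask(t_ba, kind, length(vox), grid, vox))
    m$source_runs <- run_ids
    m
  }
  list(P001 = one("P001"), FWE05 = one("FWE05"), fit = fit,
       tmap_ab = t_ab, tmap_ba = t_ba)
}

#' Split-half feature masks from the Day-1 runs
#'
#' Fits the GLM separately on the odd-numbered and even-numbered runs and
#' returns one mask pair per threshold level. The mask fitted on the odd
#' runs is meant to select features for classifiers trained on the even
#' runs, and vice versa, so feature selection never sees the training data.
#'
#' @param day1_runs list of raw Day-1 `bold_run`s (even count, >= 2).
#' @param cfg a [glm_config()].
#' @param smooth_fwhm_mm smoothing FWHM for the GLM branch.
#' @return List `P001` / `FWE05`, each with `odd` and `even` feature masks.
#' @export
split_half_masks <- function(day1_runs, cfg = glm_config(),
                             smooth_fwhm_mm = 8) {
  if (length(day1_runs) < 2 || length(day1_runs) %% 2 != 0)
    stop_config("split-half selection needs an even number (>= 2) of runs")
  ids <- vapply(day1_runs, function(r) r$schedule$run_id, 0L)
  odd <- glm_select_masks(day1_runs[ids %% 2 == 1], cfg, smooth_fwhm_mm)
  even <- glm_select_masks(day1_runs[ids %% 2 == 0], cfg, smooth_fwhm_mm)
  list(P001 = list(odd = odd$P001, even = even$P001),
       FWE05 = list(odd = odd$FWE05, even = even$FWE05))
}
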