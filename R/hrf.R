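# Canonical hemodynamic response function and task-regressor construction.

#' Canonical double-gamma HRF
#'
#' The widely used double-gamma parameterization: a gamma density peaking
#' near 5-6 s minus a later gamma undershoot scaled by `p2u_ratio`. The
#' kernel is sampled on `t = 0, tr, 2*tr, ...` up to (but excluding)
#' `duration`, and normalized so that its peak value is 1.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel length in seconds (default 32).
#' @param peak_delay,peak_disp gamma shape/scale of the response peak.
#' @param undershoot_delay,undershoot_disp gamma shape/scale of the
#'   undershoot.
#' @param p2u_ratio peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of `duration / tr` samples.
#' @export
#' @examples
#' h <- canonical_hrf(2)       # 16 samples, peak value 1
#' length(h); max(h)
canonical_hrf <- function(tr, duration = 32, peak_delay = 6, peak_disp = 1,
                          undershoot_delay = 16, undershoot_disp = 1,
                          p2u_ratio = 6) {
  if (tr <= 0) stop_config("tr must be positive")
  if (duration < tr) stop_config("duration must be at least tr")
  t <- seq(0, duration - tr, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / p2u_ratio
  h / max(h)
}

#' Convolved task regressor
#'
#' Builds the predicted BOLD response for a set of task blocks: a boxcar
#' (1 during each block, 0 elsewhere) convolved with the canonical HRF on a
#' fine time grid, then sampled at scan times `t_i = i * tr`. The regressor
#' is scaled so that a sustained block plateaus at 1, which lets planted
#' effect sizes be read directly as fractional signal change.
#'
#' @param onsets block onset times in seconds.
#' @param durations block durations in seconds (recycled to match onsets).
#' @param n_scans number of scans in the run.
#' @param tr repetition time in seconds.
#' @param oversample fine-grid subdivisions per TR used for the convolution.
#' @param ... further arguments passed to [canonical_hrf()].
#' @return Numeric vector of length `n_scans`.
#' @export
convolved_regressor <- function(onsets, durations, n_scans, tr,
                                oversample = 16L, ...) {
  if (length(onsets) == 0) return(numeric(n_scans))
  durations <- rep_len(durations, length(onsets))
  dt <- tr / oversample
  n_fine <- n_scans * oversample
  u <- numeric(n_fine)
  tf <- (seq_len(n_fine) - 1) * dt
  for (i in seq_along(onsets)) {
    u[tf >= onsets[i] - dt / 2 & tf < onsets[i] + durations[i] - dt / 2] <- 1
  }
  k <- canonical_hrf(dt, ...)
  x_fine <- stats::convolve(u, rev(k), type = "open")[seq_len(n_fine)]
  x_fine <- x_fine / sum(k)   # unit plateau for sustained blocks
  x_fine[(seq_len(n_scans) - 1) * oversample + 1]
}
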