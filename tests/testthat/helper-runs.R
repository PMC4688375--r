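# Shared fixtures, all generated in code at test time.

quiet_preprocess <- function(runs, ...) {
  suppressWarnings(preprocess_day(runs, ...))
}

# silent noise: deterministic forward model only
no_noise <- function() {
  noise_config(sigma = 0, ar1_rho = 0, drift_amplitude = 0,
               global_fluct_sd = 0, motion_coupling = 0,
               confound_amplitude = 0)
}

# small grid protocol for replicate-heavy properties
small_protocol <- function(...) {
  default_protocol(acq = acq_params(grid_shape = c(8L, 8L, 6L)), ...)
}

# a minimal bold_run wrapping an arbitrary scans x voxels matrix, with
# caller-supplied confounds; used to unit-test preprocessing operations
make_matrix_run <- function(M, mask, tr = 2, confounds = NULL) {
  g <- dim(mask)
  n <- nrow(M)
  acq <- acq_params(tr_seconds = tr, n_dummy_scans = 0, grid_shape = g)
  events <- data.frame(onset = 0, duration = n * tr, trial_type = "REST",
                       acknowledged = TRUE, stringsAsFactors = FALSE)
  sched <- scandecode:::new_run_schedule(1L, 1L, "ALTERNATING", acq, events)
  if (is.null(confounds)) {
    confounds <- as.data.frame(matrix(rnorm(n * 3), n, 3,
                                      dimnames = list(NULL, c("c1", "c2", "c3"))))
  }
  structure(list(data = array(t(M), dim = c(g, n)), schedule = sched,
                 confounds = confounds, brain_mask = mask,
                 n_dummy_dropped = 0L,
                 provenance = list(steps = character())),
            class = "bold_run")
}

all_true_mask <- function(g) array(TRUE, dim = g)
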