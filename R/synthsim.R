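# Synthetic BOLD simulator with planted two-class discriminative structure.
#
# The simulator emulates the study conditions: two days of runs, alternating
# 32 s blocks of a countdown task (TASK_A, "yes") and a positive-memory
# recall task (TASK_B, "no") separated by 16 s rests, and binary-answer runs
# in which each sentence's response window carries the task that encodes the
# factual answer. Two partially overlapping smooth activation blobs give each
# task a preferred voxel population, so both directed GLM contrasts select
# voxels downstream.

#' Ground-truth activation maps
#'
#' Builds an ellipsoidal brain mask on the acquisition grid with two
#' overlapping Gaussian activation blobs: `beta_a` (fractional signal
#' change under TASK_A) peaks in one hemisphere-analogue, `beta_b` in the
#' other. Both maps are zero outside the mask.
#'
#' @param acq [acq_params()] object (supplies the grid).
#' @param baseline baseline BOLD intensity (arbitrary units).
#' @param beta_max peak fractional signal change of each blob.
#' @param blob_sd fractional width (SD relative to grid extent) of each blob.
#' @return Object of class `ground_truth` with fields `beta_a`, `beta_b`
#'   (3D arrays), `brain_mask` (logical 3D array), `baseline`, `acq`.
#' @export
ground_truth <- function(acq = acq_params(), baseline = 1000,
                         beta_max = 0.04, blob_sd = 0.15) {
  g <- acq$grid_shape
  cx <- (seq_len(g[1]) - 0.5) / g[1]
  cy <- (seq_len(g[2]) - 0.5) / g[2]
  cz <- (seq_len(g[3]) - 0.5) / g[3]
  X <- array(rep(cx, times = g[2] * g[3]), dim = g)
  Y <- array(rep(rep(cy, each = g[1]), times = g[3]), dim = g)
  Z <- array(rep(cz, each = g[1] * g[2]), dim = g)
  mask <- ((X - 0.5) / 0.45)^2 + ((Y - 0.5) / 0.45)^2 +
    ((Z - 0.5) / 0.45)^2 <= 1
  blob <- function(ctr) {
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
    b <- beta_max * exp(-d2 / (2 * blob_sd^2))
    # compact support: clip the far tail so non-activated voxels are
    # exactly zero (numerically tiny activations would otherwise be
    # inflated into junk features by day-level standardization)
    b[b < 0.01 * beta_max] <- 0
    b[!mask] <- 0
    b
  }
  structure(list(beta_a = blob(c(0.36, 0.5, 0.5)),
                 beta_b = blob(c(0.64, 0.5, 0.5)),
                 brain_mask = mask, baseline = baseline, acq = acq),
            class = "ground_truth")
}

#' Noise configuration for the simulator
#'
#' All amplitudes are expressed as fractions of the baseline intensity.
#'
#' @param sigma SD of the voxelwise AR(1) Gaussian noise (default 0.01,
#'   i.e. a temporal SNR of 100).
#' @param ar1_rho lag-1 autocorrelation of the voxel noise, in `[0, 1)`.
#' @param drift_amplitude amplitude of the slow per-run cosine drift.
#' @param global_fluct_sd SD of the shared global AR(1) fluctuation added
#'   to every in-mask voxel.
#' @param motion_coupling amplitude of the motion-coupled signal component.
#' @param confound_amplitude scale of the simulated confound series
#'   themselves (motion random walks, white-matter/CSF proxies); 0 gives a
#'   fully deterministic run, which is what "noiseless" should mean —
#'   stochastic nuisance regressors would otherwise distort even noise-free
#'   data when they are regressed out.
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(sigma = 0.01, ar1_rho = 0.3,
                         drift_amplitude = 0.01, global_fluct_sd = 0.005,
                         motion_coupling = 0.005, confound_amplitude = 1) {
  if (abs(ar1_rho) >= 1) stop_config("ar1_rho must satisfy |rho| < 1")
  if (any(c(sigma, drift_amplitude, global_fluct_sd, motion_coupling,
            confound_amplitude) < 0))
    stop_config("noise amplitudes must be non-negative")
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 global_fluct_sd = global_fluct_sd,
                 motion_coupling = motion_coupling,
                 confound_amplitude = confound_amplitude),
            class = "noise_config")
}

ar1_series <- function(n, rho, sd_stationary) {
  if (sd_stationary == 0) return(numeric(n))
  innov_sd <- sd_stationary * sqrt(1 - rho^2)
  e <- stats::rnorm(n, sd = innov_sd)
  e[1] <- stats::rnorm(1, sd = sd_stationary)
  as.numeric(stats::filter(e, rho, method = "recursive", init = 0))
}

# task boxcar onsets/durations implied by a schedule; for binary runs the
# response window carries the task matching the trial's factual answer
task_onsets <- function(schedule) {
  ev <- schedule$events
  if (schedule$kind == "ALTERNATING") {
    a <- ev[ev$trial_type == "TASK_A", , drop = FALSE]
    b <- ev[ev$trial_type == "TASK_B", , drop = FALSE]
    list(a_onsets = a$onset, a_durations = a$duration,
         b_onsets = b$onset, b_durations = b$duration)
  } else {
    tr <- schedule$trials
    yes <- tr$true_answer == "YES"
    list(a_onsets = tr$prompt_onset_seconds[yes],
         a_durations = tr$response_duration_seconds[yes],
         b_onsets = tr$prompt_onset_seconds[!yes],
         b_durations = tr$response_duration_seconds[!yes])
  }
}

#' Simulate one BOLD run
#'
#' Forward model per voxel v and scan t:
#' `baseline * (1 + beta_a(v) x_a(t) + beta_b(v) x_b(t))` plus a slow
#' cosine drift, a shared global AR(1) fluctuation, a motion-coupled
#' component, and voxelwise AR(1) Gaussian noise; `x_a`, `x_b` are task
#' boxcars convolved with the canonical HRF. Out-of-mask voxels are zero.
#' Deterministic given `seed`.
#'
#' @param schedule a `run_schedule`.
#' @param truth a [ground_truth()] object on the same grid.
#' @param noise a [noise_config()].
#' @param seed integer RNG seed for this run.
#' @return Object of class `bold_run` with fields `data` (4D array),
#'   `schedule`, `confounds` (one row per scan: 6 motion parameters,
#'   `wm_mean`, `csf_mean`, `global_mean`), `brain_mask`,
#'   `n_dummy_dropped`, `provenance`.
#' @export
simulate_run <- function(schedule, truth, noise = noise_config(), seed = 1L) {
  stopifnot(inherits(schedule, "run_schedule"),
            inherits(truth, "ground_truth"))
  if (!identical(schedule$acquisition$grid_shape, truth$acq$grid_shape))
    stop_config("schedule and ground-truth grids do not match")
  g <- schedule$acquisition$grid_shape
  n <- schedule$n_scans
  tr <- schedule$acquisition$tr_seconds
  V <- prod(g)
  in_mask <- which(truth$brain_mask)
  base <- truth$baseline

  ons <- task_onsets(schedule)
  x_a <- convolved_regressor(ons$a_onsets, ons$a_durations, n, tr)
  x_b <- convolved_regressor(ons$b_onsets, ons$b_durations, n, tr)

  M <- matrix(0, n, V)
  beta_a <- as.numeric(truth$beta_a)[in_mask]
  beta_b <- as.numeric(truth$beta_b)[in_mask]
  M[, in_mask] <- base * (1 + outer(x_a, beta_a) + outer(x_b, beta_b))

  conf <- with_seed(seed, {
    t_sec <- (seq_len(n) - 1) * tr

    # slow cosine drift, one random phase per run, per-voxel amplitude
    if (noise$drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      dcos <- cos(pi * t_sec / (n * tr) + phase)
      amp <- stats::runif(length(in_mask), 0.5, 1.5) *
        noise$drift_amplitude * base
      M[, in_mask] <- M[, in_mask] + outer(dcos, amp)
    }

    # shared global fluctuation
    gl <- ar1_series(n, 0.5, noise$global_fluct_sd * base)
    if (noise$global_fluct_sd > 0)
      M[, in_mask] <- M[, in_mask] + gl

    # motion parameters: smoothed Gaussian random walks
    ca <- noise$confound_amplitude %||% 1
    motion <- sapply(ca * c(0.02, 0.02, 0.02, 5e-4, 5e-4, 5e-4), function(s) {
      if (s == 0) return(numeric(n))
      w <- cumsum(stats::rnorm(n, sd = s))
      as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE))
    })
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")

    if (noise$motion_coupling > 0 && any(motion != 0)) {
      L <- matrix(stats::rnorm(length(in_mask) * 6), ncol = 6)
      Zm <- scale(motion)
      M[, in_mask] <- M[, in_mask] +
        noise$motion_coupling * base * (Zm %*% t(L)) / sqrt(6)
    }

    # independent slow wm/csf nuisance series (no anatomy in the synthetic
    # world; these exist so the nuisance regression has real targets)
    slow <- function() {
      if (ca == 0) return(numeric(n))
      ph <- stats::runif(1, 0, 2 * pi)
      ca * (cos(2 * pi * t_sec / 120 + ph) + 0.2 * stats::rnorm(n))
    }
    wm <- slow(); csf <- slow()

    if (noise$sigma > 0) {
      E <- matrix(stats::rnorm(n * length(in_mask),
                               sd = noise$sigma * base *
                                 sqrt(1 - noise$ar1_rho^2)),
                  n, length(in_mask))
      if (noise$ar1_rho != 0)
        E <- apply(E, 2, function(e)
          as.numeric(stats::filter(e, noise$ar1_rho,
                                   method = "recursive", init = 0)))
      M[, in_mask] <- M[, in_mask] + E
    }

    data.frame(motion, wm_mean = wm, csf_mean = csf)
  })
  conf$global_mean <- rowMeans(M[, in_mask, drop = FALSE])

  structure(list(data = array(t(M), dim = c(g, n)),
                 schedule = schedule,
                 confounds = conf,
                 brain_mask = truth$brain_mask,
                 n_dummy_dropped = 0L,
                 provenance = list(seed = seed, noise = unclass(noise),
                                   steps = "simulate")),
            class = "bold_run")
}

#' Built-in sentence set and factual answer keys
#'
#' Six example yes/no sentences with the factual answers of five
#' hypothetical respondents (columns `P1`-`P5`). The default protocol uses
#' key `P1`.
#'
#' @return Data frame with columns `sentence_id`, `text`, `P1`..`P5`.
#' @export
binary_sentences <- function() {
  data.frame(
    sentence_id = 1:6,
    text = c("You are a female",
             "Your age is an even number",
             "The month you were born is an odd number",
             "Your age is an odd number",
             "You are a male",
             "The month you were born is an even number"),
    P1 = c("YES", "NO", "YES", "YES", "NO", "NO"),
    P2 = c("NO", "YES", "YES", "NO", "YES", "NO"),
    P3 = c("NO", "NO", "YES", "YES", "YES", "NO"),
    P4 = c("NO", "NO", "YES", "YES", "YES", "NO"),
    P5 = c("NO", "YES", "NO", "NO", "YES", "YES"),
    stringsAsFactors = FALSE)
}

#' Default experiment protocol
#'
#' The study conditions simulated by default: Day 1 has 8 alternating runs
#' (3 cycles of 32 s TASK_A / 16 s rest / 32 s TASK_B / 16 s rest after a
#' 3-scan lead-in; 147 scans at TR = 2 s), Day 2 has 3 alternating runs
#' plus 5 binary-answer runs (6 sentences; 12 s sentence-to-prompt, 24 s
#' response, 16 s rest; 159 scans).
#'
#' @param acq [acq_params()] object.
#' @param n_day1_runs,n_day2_alt_runs,n_day2_binary_runs run counts.
#' @param n_cycles,task_seconds,rest_seconds alternating-run timing.
#' @param pre_prompt_seconds,response_seconds binary-run trial timing.
#' @param answer_key per-sentence factual answers (default: respondent `P1`
#'   of [binary_sentences()]).
#' @param baseline,beta_max ground-truth signal parameters.
#' @param noise a [noise_config()].
#' @param missed_blocks optional data frame with columns `run`,
#'   `trial_type`, `ordinal`: Day-1 blocks whose start cue goes
#'   unacknowledged.
#' @return A named list of protocol settings.
#' @export
default_protocol <- function(acq = acq_params(),
                             n_day1_runs = 8, n_day2_alt_runs = 3,
                             n_day2_binary_runs = 5,
                             n_cycles = 3, task_seconds = 32,
                             rest_seconds = 16,
                             pre_prompt_seconds = 12, response_seconds = 24,
                             answer_key = binary_sentences()$P1,
                             baseline = 1000, beta_max = 0.04,
                             noise = noise_config(),
                             missed_blocks = NULL) {
  list(acq = acq, n_day1_runs = n_day1_runs,
       n_day2_alt_runs = n_day2_alt_runs,
       n_day2_binary_runs = n_day2_binary_runs,
       n_cycles = n_cycles, task_seconds = task_seconds,
       rest_seconds = rest_seconds,
       pre_prompt_seconds = pre_prompt_seconds,
       response_seconds = response_seconds,
       answer_key = normalize_answers(answer_key),
       baseline = baseline, beta_max = beta_max, noise = noise,
       missed_blocks = missed_blocks)
}

#' Simulate the full two-day experiment
#'
#' Builds all run schedules from the protocol, derives one sub-seed per run
#' from the master seed, and simulates every run against a common ground
#' truth.
#'
#' @param protocol a [default_protocol()]-style list.
#' @param truth optional [ground_truth()]; built from the protocol if NULL.
#' @param seed master integer seed.
#' @return Object of class `sim_experiment` with fields `day1`, `day2_alt`,
#'   `day2_binary` (lists of `bold_run`), `truth`, `protocol`, `seed`.
#' @export
simulate_experiment <- function(protocol = default_protocol(), truth = NULL,
                                seed = 1L) {
  if (is.null(truth))
    truth <- ground_truth(protocol$acq, baseline = protocol$baseline,
                          beta_max = protocol$beta_max)
  counter <- 0L
  sim <- function(sched) {
    counter <<- counter + 1L
    simulate_run(sched, truth, protocol$noise,
                 seed = derive_seed(seed, counter))
  }
  mk_alt <- function(run_id, day) {
    s <- build_alternating_run(protocol$acq, protocol$n_cycles,
                               protocol$task_seconds, protocol$rest_seconds,
                               run_id = run_id, day = day)
    if (day == 1 && !is.null(protocol$missed_blocks)) {
      mb <- protocol$missed_blocks
      for (i in seq_len(nrow(mb))) {
        if (mb$run[i] == run_id)
          s <- mark_unacknowledged(s, mb$trial_type[i], mb$ordinal[i])
      }
    }
    s
  }
  day1 <- lapply(seq_len(protocol$n_day1_runs),
                 function(r) sim(mk_alt(r, 1L)))
  day2_alt <- lapply(seq_len(protocol$n_day2_alt_runs),
                     function(r) sim(mk_alt(r, 2L)))
  day2_binary <- lapply(seq_len(protocol$n_day2_binary_runs), function(r) {
    sim(build_binary_answer_run(protocol$acq, protocol$answer_key,
                                protocol$pre_prompt_seconds,
                                protocol$response_seconds,
                                protocol$rest_seconds,
                                run_id = r + protocol$n_day2_alt_runs,
                                day = 2L))
  })
  structure(list(day1 = day1, day2_alt = day2_alt,
                 day2_binary = day2_binary, truth = truth,
                 protocol = protocol, seed = seed),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(paste0("<sim_experiment> seed %d: %d day-1 runs, %d day-2 ",
                     "alternating runs, %d binary-answer runs; grid %s\n"),
              x$seed, length(x$day1), length(x$day2_alt),
              length(x$day2_binary),
              paste(x$protocol$acq$grid_shape, collapse = "x")))
  invisible(x)
}
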