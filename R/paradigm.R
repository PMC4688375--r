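# Experiment paradigm: run schedules and scan-count bookkeeping.
#
# Scan indices follow a 0-based convention throughout: the scan at index i
# covers the half-open interval [i*TR, (i+1)*TR) seconds from run start,
# and index 0 is the first dummy (lead-in) scan. Half-open intervals make
# all window arithmetic exact. Helpers that slice data arrays convert to
# R's 1-based indexing internally.

#' Acquisition parameters
#'
#' Describes the sampling grid of one functional run: repetition time,
#' number of lead-in (dummy) scans discarded before analysis, and the
#' voxel grid.
#'
#' @param tr_seconds repetition time in seconds (time per whole-brain scan).
#' @param n_dummy_scans number of lead-in scans acquired before the task
#'   starts; kept in schedules and raw data, discarded at analysis time.
#' @param grid_shape integer vector of 3 voxel-grid dimensions.
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm.
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq_params()  # 2 s TR, 3 dummies, small synthetic grid
acq_params <- function(tr_seconds = 2, n_dummy_scans = 3,
                       grid_shape = c(12L, 12L, 8L),
                       voxel_size_mm = c(3, 3, 5)) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop_config("tr_seconds must be a single positive number")
  if (n_dummy_scans < 0 || n_dummy_scans != round(n_dummy_scans))
    stop_config("n_dummy_scans must be a non-negative integer")
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop_config("grid_shape must be 3 positive integers")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stop_config("voxel_size_mm must be 3 positive numbers")
  structure(list(tr_seconds = tr_seconds,
                 n_dummy_scans = as.integer(n_dummy_scans),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "acq_params")
}

new_run_schedule <- function(run_id, day, kind, acquisition, events,
                             trials = NULL) {
  tr <- acquisition$tr_seconds
  # events must tile the run contiguously
  if (nrow(events) > 1) {
    gaps <- events$onset[-1] - (events$onset[-nrow(events)] +
                                  events$duration[-nrow(events)])
    if (any(abs(gaps) > 1e-9))
      stop_config("schedule events must be contiguous and non-overlapping")
  }
  duration <- sum(events$duration)
  if (!is_multiple_of(duration, tr))
    stop_config("run duration must be a multiple of TR")
  structure(list(run_id = as.integer(run_id), day = as.integer(day),
                 kind = kind, acquisition = acquisition, events = events,
                 trials = trials,
                 n_scans = as.integer(round(duration / tr)),
                 duration_seconds = duration),
            class = "run_schedule")
}

#' Build an alternating two-task run schedule
#'
#' One run consists of the dummy lead-in followed by `n_cycles` repetitions
#' of TASK_A block, rest, TASK_B block, rest. With the default timing
#' (TR = 2 s, 3 dummies, 32 s blocks, 16 s rests, 3 cycles) a run lasts
#' 294 s = 147 scans.
#'
#' @param acq [acq_params()] object.
#' @param n_cycles number of TASK_A/rest/TASK_B/rest cycles.
#' @param task_seconds task block duration (multiple of TR).
#' @param rest_seconds rest duration (multiple of TR).
#' @param run_id,day identifiers stored in the schedule.
#' @return A `run_schedule` of kind `"ALTERNATING"`.
#' @export
#' @examples
#' sched <- build_alternating_run(acq_params())
#' sched$n_scans  # 147
build_alternating_run <- function(acq, n_cycles = 3, task_seconds = 32,
                                  rest_seconds = 16, run_id = 1L, day = 1L) {
  stopifnot(inherits(acq, "acq_params"))
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop_config("n_cycles must be a non-negative integer")
  tr <- acq$tr_seconds
  if (task_seconds <= 0 || !is_multiple_of(task_seconds, tr))
    stop_config("task_seconds must be a positive multiple of TR")
  if (rest_seconds <= 0 || !is_multiple_of(rest_seconds, tr))
    stop_config("rest_seconds must be a positive multiple of TR")

  onset <- 0
  rows <- list()
  add <- function(type, dur) {
    rows[[length(rows) + 1]] <<- data.frame(
      onset = onset, duration = dur, trial_type = type,
      acknowledged = TRUE, stringsAsFactors = FALSE)
    onset <<- onset + dur
  }
  if (acq$n_dummy_scans > 0) add("DUMMY", acq$n_dummy_scans * tr)
  if (n_cycles > 0) {
    for (i in seq_len(n_cycles)) {
      add("TASK_A", task_seconds)
      add("REST", rest_seconds)
      add("TASK_B", task_seconds)
      add("REST", rest_seconds)
    }
  }
  events <- do.call(rbind, rows)
  new_run_schedule(run_id, day, "ALTERNATING", acq, events)
}

#' Build a binary-answer run schedule
#'
#' Each sentence trial is: sentence playback / thinking period
#' (`pre_prompt_seconds`), then the answer prompt opens a response window of
#' `response_seconds` during which the participant performs the task
#' encoding yes or no, then rest. With defaults (6 sentences, 12/24/16 s)
#' a run lasts 318 s = 159 scans.
#'
#' The factual answers in `answer_key` are stored in the schedule's `trials`
#' table as simulation ground truth and for scoring only; no decoding
#' operation reads them.
#'
#' @param acq [acq_params()] object.
#' @param answer_key character vector of `"YES"`/`"NO"` per sentence.
#' @param pre_prompt_seconds delay from sentence onset to answer prompt.
#' @param response_seconds response-window duration.
#' @param rest_seconds rest after each response window.
#' @param run_id,day identifiers stored in the schedule.
#' @return A `run_schedule` of kind `"BINARY_ANSWER"` with a `trials` table.
#' @export
#' @examples
#' sched <- build_binary_answer_run(acq_params(), c("YES", "NO"))
#' sched$trials
build_binary_answer_run <- function(acq, answer_key,
                                    pre_prompt_seconds = 12,
                                    response_seconds = 24,
                                    rest_seconds = 16,
                                    run_id = 1L, day = 2L) {
  stopifnot(inherits(acq, "acq_params"))
  answer_key <- normalize_answers(answer_key)
  if (length(answer_key) == 0)
    stop_config("answer_key must be non-empty")
  tr <- acq$tr_seconds
  for (v in c(pre_prompt_seconds, response_seconds, rest_seconds)) {
    if (v <= 0 || !is_multiple_of(v, tr))
      stop_config("trial timing values must be positive multiples of TR")
  }

  onset <- 0
  rows <- list()
  add <- function(type, dur, ack = TRUE) {
    rows[[length(rows) + 1]] <<- data.frame(
      onset = onset, duration = dur, trial_type = type,
      acknowledged = ack, stringsAsFactors = FALSE)
    onset <<- onset + dur
  }
  if (acq$n_dummy_scans > 0) add("DUMMY", acq$n_dummy_scans * tr)
  trials <- vector("list", length(answer_key))
  for (s in seq_along(answer_key)) {
    sentence_onset <- onset
    add("SENTENCE", pre_prompt_seconds)
    prompt_onset <- onset
    add("RESPONSE", response_seconds)
    add("REST", rest_seconds)
    trials[[s]] <- data.frame(
      sentence_id = s,
      sentence_onset_seconds = sentence_onset,
      prompt_onset_seconds = prompt_onset,
      response_duration_seconds = response_seconds,
      true_answer = answer_key[s],
      stringsAsFactors = FALSE)
  }
  new_run_schedule(run_id, day, "BINARY_ANSWER", acq,
                   do.call(rbind, rows), do.call(rbind, trials))
}

normalize_answers <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "YES", "NO")
  x <- toupper(as.character(x))
  if (!all(x %in% c("YES", "NO")))
    stop_config("answers must be YES or NO")
  x
}

#' Count training scans per class
#'
#' Design arithmetic for the training set: each task block of 32 s
#' contributes 16 scans at TR = 2 s, each run has 3 blocks per task, so 8
#' fully acknowledged runs contribute 384 scans per class (192 when
#' training on half the runs).
#'
#' @param n_runs number of runs contributing.
#' @param blocks_per_task_per_run blocks of each task per run.
#' @param scans_per_block scans retained per block.
#' @return Integer scan count per class.
#' @export
#' @examples
#' count_training_scans(8, 3, 16)  # 384
count_training_scans <- function(n_runs, blocks_per_task_per_run,
                                 scans_per_block) {
  args <- c(n_runs, blocks_per_task_per_run, scans_per_block)
  if (any(args < 0) || any(args != round(args)))
    stop_config("all arguments must be non-negative integers")
  as.integer(n_runs) * as.integer(blocks_per_task_per_run) *
    as.integer(scans_per_block)
}

#' Response-period scan indices
#'
#' Maps each sentence trial of a binary-answer run to the scans in its
#' response window, shifted by `shift_seconds` to account for hemodynamic
#' delay (default 4 s = 2 TRs). Indices are 0-based over the full run
#' including dummy scans; a window of 24 s yields exactly 12 indices.
#'
#' @param schedule a `run_schedule` of kind `"BINARY_ANSWER"`.
#' @param shift_seconds hemodynamic shift, a multiple of TR.
#' @return List (one element per trial) of 0-based integer scan indices.
#' @export
response_scan_indices <- function(schedule, shift_seconds = 4) {
  stopifnot(inherits(schedule, "run_schedule"))
  if (schedule$kind != "BINARY_ANSWER")
    stop_config("response_scan_indices requires a BINARY_ANSWER schedule")
  tr <- schedule$acquisition$tr_seconds
  if (!is_multiple_of(shift_seconds, tr))
    stop_config("shift_seconds must be a multiple of TR")
  out <- lapply(seq_len(nrow(schedule$trials)), function(s) {
    tr_row <- schedule$trials[s, ]
    start <- (tr_row$prompt_onset_seconds + shift_seconds) / tr
    n <- tr_row$response_duration_seconds / tr
    idx <- as.integer(round(start)) + seq_len(round(n)) - 1L
    if (any(idx < 0) || any(idx >= schedule$n_scans))
      stop_config("shifted response window falls outside the run")
    idx
  })
  names(out) <- paste0("trial_", schedule$trials$sentence_id)
  out
}

#' Task-block scan windows of an alternating run
#'
#' Returns, for every TASK_A/TASK_B block, the 0-based indices of the scans
#' attributed to it: the window `[onset + shift, onset + duration + shift)`.
#' With 32 s blocks this is 16 scans per block.
#'
#' @param schedule a `run_schedule` of kind `"ALTERNATING"`.
#' @param shift_seconds hemodynamic shift, a multiple of TR.
#' @return Data-frame-backed list with one element per task block holding
#'   `label`, `ordinal` (position among blocks of the same task),
#'   `acknowledged`, and `indices`.
#' @export
block_scan_indices <- function(schedule, shift_seconds = 4) {
  stopifnot(inherits(schedule, "run_schedule"))
  if (schedule$kind != "ALTERNATING")
    stop_config("block_scan_indices requires an ALTERNATING schedule")
  tr <- schedule$acquisition$tr_seconds
  if (!is_multiple_of(shift_seconds, tr))
    stop_config("shift_seconds must be a multiple of TR")
  ev <- schedule$events
  task <- ev[ev$trial_type %in% c("TASK_A", "TASK_B"), , drop = FALSE]
  counters <- c(TASK_A = 0L, TASK_B = 0L)
  out <- vector("list", nrow(task))
  for (i in seq_len(nrow(task))) {
    lab <- task$trial_type[i]
    counters[lab] <- counters[lab] + 1L
    start <- (task$onset[i] + shift_seconds) / tr
    n <- task$duration[i] / tr
    idx <- as.integer(round(start)) + seq_len(round(n)) - 1L
    if (any(idx < 0) || any(idx >= schedule$n_scans))
      stop_config("shifted block window falls outside the run")
    out[[i]] <- list(label = lab, ordinal = counters[[lab]],
                     acknowledged = task$acknowledged[i], indices = idx)
  }
  out
}

#' Mark a task block as unacknowledged
#'
#' Flips `acknowledged = FALSE` on the `ordinal`-th block of `trial_type`
#' in the schedule, emulating a missed button press to the task-start cue.
#'
#' @param schedule a `run_schedule`.
#' @param trial_type `"TASK_A"` or `"TASK_B"`.
#' @param ordinal which block of that task (1-based).
#' @return The modified schedule.
#' @export
mark_unacknowledged <- function(schedule, trial_type, ordinal) {
  ev <- schedule$events
  hits <- which(ev$trial_type == trial_type)
  if (ordinal < 1 || ordinal > length(hits))
    stop_config("no such block: ", trial_type, " #", ordinal)
  schedule$events$acknowledged[hits[ordinal]] <- FALSE
  schedule
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("<run_schedule> run %d, day %d, %s: %d scans (%.0f s, TR %.3g s)\n",
              x$run_id, x$day, x$kind, x$n_scans, x$duration_seconds,
              x$acquisition$tr_seconds))
  tab <- table(x$events$trial_type)
  cat("  events:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$trials))
    cat("  trials:", nrow(x$trials), "sentences\n")
  invisible(x)
}

#' Write / read a run's events table as tab-separated text
#'
#' The events file has columns `onset`, `duration`, `trial_type`,
#' `acknowledged`, `true_answer` (the last is `n/a` except on RESPONSE
#' rows of binary-answer runs).
#'
#' @param schedule a `run_schedule`.
#' @param path output file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the events data frame (with `true_answer` where present).
#' @export
write_events <- function(schedule, path) {
  ev <- schedule$events
  ev$true_answer <- "n/a"
  if (!is.null(schedule$trials)) {
    resp <- which(ev$trial_type == "RESPONSE")
    ev$true_answer[resp] <- schedule$trials$true_answer
  }
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
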