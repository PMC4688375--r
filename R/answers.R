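# Answer retrieval: classify response-period scans, vote, score against the
# factual key, and trace performance as a function of response duration.

#' Voting configuration
#'
#' @param k scans used per response period in the majority vote; must be
#'   odd so no vote can tie (default 11 of the 12 available).
#' @param k_grid odd scan counts for the duration-effect curve.
#' @return Object of class `vote_config`.
#' @export
vote_config <- function(k = 11, k_grid = c(3, 5, 7, 9, 11)) {
  if (k %% 2 == 0 || any(k_grid %% 2 == 0))
    stop_config("k and every entry of k_grid must be odd")
  structure(list(k = as.integer(k), k_grid = as.integer(k_grid)),
            class = "vote_config")
}

#' Classify the response-period scans of binary-answer runs
#'
#' For each sentence the shifted response-window scans (12 for a 24 s
#' window at TR = 2 s) are extracted at the classifier's feature voxels,
#' scaled with its training scaler, and labeled by the sign of the decision
#' value (0 maps to +1). Ground-truth answers are never read here.
#'
#' @param model a `scan_classifier`.
#' @param runs list of preprocessed (dummy-stripped) BINARY_ANSWER
#'   `bold_run`s.
#' @param shift_seconds hemodynamic shift (default 4).
#' @return Object of class `response_predictions`: arrays `values` and
#'   `labels` of dim (run, sentence, scan), plus `run_ids`.
#' @export
classify_response_periods <- function(model, runs, shift_seconds = 4) {
  stopifnot(length(runs) >= 1)
  if (!identical(prod(model$mask_ref$grid),
                 prod(dim(runs[[1]]$data)[1:3])))
    stop_config("classifier mask grid does not match the runs")
  n_sent <- nrow(runs[[1]]$schedule$trials)
  idx0 <- response_scan_indices(runs[[1]]$schedule, shift_seconds)
  n_per <- length(idx0[[1]])
  values <- array(NA_real_, dim = c(length(runs), n_sent, n_per))
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    idx <- response_scan_indices(run$schedule, shift_seconds)
    M <- run_matrix(run)
    for (s in seq_len(n_sent)) {
      i1 <- idx[[s]] - run$n_dummy_dropped + 1L
      if (any(i1 < 1) || any(i1 > nrow(M)))
        stop_config("response window falls outside retained scans")
      pred <- predict_scans(model, M[i1, model$mask_ref$voxels,
                                     drop = FALSE])
      values[r, s, ] <- pred$values
    }
  }
  structure(list(values = values,
                 labels = ifelse(values >= 0, 1, -1),
                 run_ids = vapply(runs, function(x) x$schedule$run_id, 0L)),
            class = "response_predictions")
}

#' Majority vote over the first k scan labels
#'
#' `"YES"` iff more than half of the first `k` labels are +1; odd `k`
#' guarantees no tie.
#'
#' @param scan_labels vector of +1 / -1 single-scan labels.
#' @param k odd number of leading scans to vote over.
#' @return `"YES"` or `"NO"`.
#' @export
majority_vote <- function(scan_labels, k) {
  if (k %% 2 == 0) stop_config("k must be odd (ties would be possible)")
  if (k < 1 || k > length(scan_labels))
    stop_config("k must be between 1 and the number of scan labels")
  if (sum(scan_labels[seq_len(k)] == 1) > k / 2) "YES" else "NO"
}

votes_from_labels <- function(labels, k) {
  apply(labels, c(1, 2), majority_vote, k = k)
}

#' Score decoded votes against the factual answer key
#'
#' @param votes run x sentence matrix of `"YES"`/`"NO"`.
#' @param answer_key per-sentence factual answers.
#' @return List with `n_correct_per_run`, `consistent_correct` (sentences
#'   correct in every run), `mean_correct`, `sd_correct`.
#' @export
score_answers <- function(votes, answer_key) {
  answer_key <- normalize_answers(answer_key)
  if (ncol(votes) != length(answer_key))
    stop_config("votes and answer key have different sentence counts")
  hits <- sweep(votes, 2, answer_key, "==")
  n_correct <- rowSums(hits)
  list(n_correct_per_run = as.integer(n_correct),
       consistent_correct = sum(colSums(hits) == nrow(votes)),
       mean_correct = mean(n_correct),
       sd_correct = stats::sd(n_correct))
}

#' Duration-effect curve
#'
#' Recomputes the majority vote from the stored per-scan labels for each
#' response-period length in `k_grid` (no re-classification) and scores
#' each against the key.
#'
#' @param pred a `response_predictions`.
#' @param answer_key per-sentence factual answers.
#' @param k_grid odd scan counts (default 3, 5, 7, 9, 11).
#' @return Data frame with columns `k`, `mean_correct`, `sd_correct`.
#' @export
duration_curve <- function(pred, answer_key, k_grid = c(3, 5, 7, 9, 11)) {
  if (any(k_grid %% 2 == 0) || any(k_grid < 1) ||
      max(k_grid) > dim(pred$labels)[3])
    stop_config("k_grid entries must be odd and within the response period")
  out <- lapply(k_grid, function(k) {
    sc <- score_answers(votes_from_labels(pred$labels, k), answer_key)
    data.frame(k = k, mean_correct = sc$mean_correct,
               sd_correct = sc$sd_correct)
  })
  do.call(rbind, out)
}

#' Decode and score the answers of binary-answer runs
#'
#' Full answer retrieval: classify every response-period scan, vote over
#' the first `k` scans of each period, score per run and for cross-run
#' consistency, compute the single-scan accuracy over all response scans,
#' and trace the duration curve. The answer key is used for scoring only.
#'
#' @param model a `scan_classifier` trained on Day-1 data.
#' @param runs preprocessed BINARY_ANSWER `bold_run`s.
#' @param answer_key per-sentence factual answers.
#' @param cfg a [vote_config()].
#' @param shift_seconds hemodynamic shift (default 4).
#' @return Object of class `decoded_answers`.
#' @export
decode_answers <- function(model, runs, answer_key, cfg = vote_config(),
                           shift_seconds = 4) {
  answer_key <- normalize_answers(answer_key)
  pred <- classify_response_periods(model, runs, shift_seconds)
  votes <- votes_from_labels(pred$labels, cfg$k)
  sc <- score_answers(votes, answer_key)
  truth_scan <- ifelse(answer_key == "YES", 1, -1)
  acc <- mean(sweep(pred$labels, 2, truth_scan, "==") )
  structure(c(list(predictions = pred, votes = votes,
                   single_scan_accuracy = acc,
                   n_response_scans = length(pred$labels),
                   duration = duration_curve(pred, answer_key, cfg$k_grid),
                   answer_key = answer_key, k = cfg$k),
              sc),
            class = "decoded_answers")
}

#' @export
print.decoded_answers <- function(x, ...) {
  cat(sprintf(paste0("<decoded_answers> %d runs x %d sentences; single-scan ",
                     "accuracy %.1f%% (%d scans)\n"),
              nrow(x$votes), ncol(x$votes), 100 * x$single_scan_accuracy,
              x$n_response_scans))
  cat(sprintf("  correct per run (k = %d): %s; mean %.1f (SD %.1f); consistent %d\n",
              x$k, paste(x$n_correct_per_run, collapse = ", "),
              x$mean_correct, x$sd_correct, x$consistent_correct))
  invisible(x)
}
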