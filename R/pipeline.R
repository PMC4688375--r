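# End-to-end orchestration: simulate -> preprocess -> (GLM select) ->
# train -> permutation test -> decode -> report. Every stage is also
# available as a standalone function and as a command-line subcommand
# (see inst/cli/scandecode.R).

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage with the master seed and
#' the feature-selection mode. `"whole_brain"` trains on all in-mask voxels
#' using all Day-1 runs; `"p001"` / `"fwe05"` use the split-half GLM masks,
#' training on the half of the runs not used for selection (both pairings
#' are evaluated and averaged).
#'
#' @param seed master integer seed.
#' @param mode `"whole_brain"`, `"p001"`, or `"fwe05"`.
#' @param protocol a [default_protocol()] list.
#' @param preproc a [preproc_config()].
#' @param glm a [glm_config()].
#' @param svm a [svm_config()].
#' @param vote a [vote_config()].
#' @param shift_seconds hemodynamic shift applied to every scan window.
#' @param n_permutations permutation count for the significance test
#'   (0 skips the test).
#' @param out_dir optional directory for the report files.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            mode = c("whole_brain", "p001", "fwe05"),
                            protocol = default_protocol(),
                            preproc = preproc_config(),
                            glm = glm_config(),
                            svm = svm_config(),
                            vote = vote_config(),
                            shift_seconds = 4,
                            n_permutations = 0L,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), mode = match.arg(mode),
                 protocol = protocol, preproc = preproc, glm = glm,
                 svm = svm, vote = vote, shift_seconds = shift_seconds,
                 n_permutations = n_permutations, out_dir = out_dir),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tf, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  unname(tools::md5sum(tf))
}

# stack the response-period scans of all binary runs into an evaluation
# matrix; truth labels come from the answer key (+1 = YES)
response_scan_matrix <- function(runs, voxels, answer_key, shift_seconds = 4) {
  answer_key <- normalize_answers(answer_key)
  Xs <- list(); ys <- list(); j <- 0
  for (run in runs) {
    idx <- response_scan_indices(run$schedule, shift_seconds)
    M <- run_matrix(run)
    for (s in seq_along(idx)) {
      i1 <- idx[[s]] - run$n_dummy_dropped + 1L
      j <- j + 1
      Xs[[j]] <- M[i1, voxels, drop = FALSE]
      ys[[j]] <- rep(if (answer_key[s] == "YES") 1 else -1, length(i1))
    }
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

#' Run the full decoding pipeline on a synthetic experiment
#'
#' Simulates the two-day experiment, preprocesses each day (multivariate
#' branch), selects features according to the configured mode, trains the
#' single-scan classifier on Day-1 data, cross-validates it
#' (leave-one-run-out), evaluates it on the Day-2 alternating runs and on
#' the binary-answer response periods, runs the balanced-block permutation
#' test when requested, and decodes the answers by majority vote.
#'
#' Deterministic: the same configuration and seed reproduce the report
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @return A report list; written as JSON (plus a votes CSV) when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$protocol
  exp <- simulate_experiment(p, seed = config$seed)
  day1 <- suppressWarnings(preprocess_day(exp$day1, config$preproc))
  n_alt2 <- length(exp$day2_alt)
  day2 <- suppressWarnings(
    preprocess_day(c(exp$day2_alt, exp$day2_binary), config$preproc))
  day2_alt <- if (n_alt2 > 0) day2[seq_len(n_alt2)] else list()
  day2_bin <- day2[seq_len(length(exp$day2_binary)) + n_alt2]
  key <- p$answer_key
  shift <- config$shift_seconds

  report <- list(
    config_digest = config_digest(config),
    seed = config$seed,
    mode = config$mode,
    design = list(
      alternating_run_scans = build_alternating_run(
        p$acq, p$n_cycles, p$task_seconds, p$rest_seconds)$n_scans,
      binary_run_scans = build_binary_answer_run(
        p$acq, key, p$pre_prompt_seconds, p$response_seconds,
        p$rest_seconds)$n_scans,
      train_scans_per_class = count_training_scans(
        p$n_day1_runs, p$n_cycles,
        as.integer(p$task_seconds / p$acq$tr_seconds)),
      half_train_scans_per_class = count_training_scans(
        p$n_day1_runs %/% 2, p$n_cycles,
        as.integer(p$task_seconds / p$acq$tr_seconds))))

  decode_with <- function(model, train_ds) {
    dec <- decode_answers(model, day2_bin, key, config$vote, shift)
    perm <- NULL
    if (config$n_permutations > 0) {
      ev <- response_scan_matrix(day2_bin, model$mask_ref$voxels, key, shift)
      perm <- balanced_block_permutation_test(
        train_ds, ev$X, ev$y, config$svm, config$n_permutations,
        seed = derive_seed(config$seed, 99L))
    }
    list(decoded = dec, permutation = perm)
  }

  if (config$mode == "whole_brain") {
    wb <- feature_mask(exp$truth$brain_mask, "WHOLE_BRAIN")
    ds <- assemble_dataset(day1, wb, shift)
    cv <- loro_cv(ds, config$svm)
    model <- train_classifier(ds, config$svm)
    alt_acc <- NA_real_
    if (n_alt2 > 0) {
      ds_alt <- assemble_dataset(day2_alt, wb, shift)
      alt_acc <- mean(predict_scans(model, ds_alt$X)$labels == ds_alt$y)
    }
    res <- decode_with(model, ds)
    dec <- res$decoded
    report$n_features <- length(model$w)
    report$day1_lorocv <- list(pooled_accuracy = cv$pooled_accuracy,
                               n_scans = sum(cv$folds$n),
                               folds = cv$folds)
    report$day2_alt_accuracy <- alt_acc
    report$binary <- list(
      single_scan_accuracy = dec$single_scan_accuracy,
      n_response_scans = dec$n_response_scans,
      mean_correct = dec$mean_correct, sd_correct = dec$sd_correct,
      n_correct_per_run = dec$n_correct_per_run,
      consistent_correct = dec$consistent_correct,
      duration_curve = dec$duration)
    report$votes <- dec$votes
    if (!is.null(res$permutation))
      report$permutation <- list(
        observed_accuracy = res$permutation$observed_accuracy,
        p_value = res$permutation$p_value,
        n_permutations = res$permutation$n_permutations)
  } else {
    kind <- toupper(sub("fwe05", "FWE05", sub("p001", "P001", config$mode)))
    masks <- split_half_masks(exp$day1, config$glm,
                              config$preproc$smooth_fwhm_mm)[[kind]]
    ids <- vapply(day1, function(r) r$schedule$run_id, 0L)
    halves <- list(
      list(mask = masks$odd, train = day1[ids %% 2 == 0], name = "even"),
      list(mask = masks$even, train = day1[ids %% 2 == 1], name = "odd"))
    per_half <- lapply(halves, function(h) {
      if (h$mask$n_voxels == 0)
        stop_config("the ", kind, " mask selected no voxels")
      ds <- assemble_dataset(h$train, h$mask, shift)
      model <- train_classifier(ds, config$svm)
      dec <- decode_answers(model, day2_bin, key, config$vote, shift)
      list(trained_on = h$name, n_features = h$mask$n_voxels,
           decoded = dec)
    })
    report$n_features <- mean(vapply(per_half, `[[`, 0, "n_features"))
    report$binary <- list(
      mean_correct = mean(vapply(per_half,
                                 function(x) x$decoded$mean_correct, 0)),
      consistent_correct = mean(vapply(per_half,
                                       function(x) x$decoded$consistent_correct, 0)),
      single_scan_accuracy = mean(vapply(per_half,
                                         function(x) x$decoded$single_scan_accuracy, 0)),
      per_half = lapply(per_half, function(x)
        list(trained_on = x$trained_on, n_features = x$n_features,
             mean_correct = x$decoded$mean_correct,
             consistent_correct = x$decoded$consistent_correct)))
    report$votes <- per_half[[1]]$decoded$votes
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "votes")],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    votes_df <- as.data.frame(report$votes)
    names(votes_df) <- paste0("sentence_", seq_len(ncol(votes_df)))
    votes_df <- cbind(run = seq_len(nrow(votes_df)), votes_df)
    utils::write.csv(votes_df, file.path(config$out_dir, "votes.csv"),
                     row.names = FALSE)
  }
  report
}
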