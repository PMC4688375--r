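# Multivariate pattern analysis: balanced dataset assembly, [-1, 1]
# feature scaling, the single-scan linear max-margin classifier,
# leave-one-run-out cross-validation, and the balanced-block permutation
# test.

#' Classifier configuration
#'
#' The classifier is the standard L2-regularized hinge-loss soft-margin
#' linear model ("linear SVM") with misclassification penalty `C = 1`.
#'
#' @param C soft-margin penalty (default 1).
#' @param tolerance solver termination tolerance.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 1, tolerance = 0.001) {
  if (C <= 0) stop_config("C must be positive")
  structure(list(C = C, tolerance = tolerance), class = "svm_config")
}

#' Assemble a balanced labeled scan set from alternating runs
#'
#' Extracts the task-block scans of each preprocessed run (windows
#' `[onset + shift, onset + block_duration + shift)`, dummy scans excluded)
#' at the feature-mask voxels. Balancing screen: if a block's start cue was
#' unacknowledged, that block AND its same-ordinal counterpart block of the
#' other task in the same run are both dropped, so class counts stay equal
#' by construction.
#'
#' @param runs list of preprocessed (dummy-stripped) ALTERNATING
#'   `bold_run`s.
#' @param mask a `feature_mask` (or logical 3D array).
#' @param shift_seconds hemodynamic shift (default 4).
#' @return Object of class `labeled_scan_set` with `X` (scans x features),
#'   `y` (+1 = TASK_A/yes, -1 = TASK_B/no), `block_id`, `run_id`,
#'   `mask_ref`.
#' @export
assemble_dataset <- function(runs, mask, shift_seconds = 4) {
  m <- if (inherits(mask, "feature_mask")) mask$mask else mask
  vox <- which(m)
  if (length(vox) == 0) stop_config("feature mask is empty")
  rows <- list(); ys <- list(); blocks <- list(); rids <- list()
  next_block <- 0L
  for (run in runs) {
    if (run$n_dummy_dropped == 0 &&
        run$schedule$acquisition$n_dummy_scans > 0)
      stop_config("runs must have dummy scans dropped before assembly")
    sched <- run$schedule
    info <- block_scan_indices(sched, shift_seconds)
    labs <- vapply(info, `[[`, "", "label")
    ords <- vapply(info, `[[`, 0L, "ordinal")
    acks <- vapply(info, `[[`, TRUE, "acknowledged")
    # a missed cue drops the block and its same-ordinal counterpart
    bad_ord <- unique(ords[!acks])
    keep <- !(ords %in% bad_ord)
    M <- run_matrix(run)
    for (i in which(keep)) {
      idx1 <- info[[i]]$indices - run$n_dummy_dropped + 1L
      if (any(idx1 < 1) || any(idx1 > nrow(M)))
        stop_config("block window falls outside retained scans")
      next_block <- next_block + 1L
      rows[[next_block]] <- M[idx1, vox, drop = FALSE]
      ys[[next_block]] <- rep(if (labs[i] == "TASK_A") 1 else -1,
                              length(idx1))
      blocks[[next_block]] <- rep(next_block, length(idx1))
      rids[[next_block]] <- rep(sched$run_id, length(idx1))
    }
  }
  if (next_block == 0L)
    stop_config("no acknowledged block pairs remain; dataset is empty")
  ds <- structure(list(X = do.call(rbind, rows),
                       y = unlist(ys),
                       block_id = unlist(blocks),
                       run_id = unlist(rids),
                       mask_ref = list(voxels = vox, grid = dim(m),
                                       kind = if (inherits(mask, "feature_mask"))
                                         mask$threshold_kind else "WHOLE_BRAIN")),
                  class = "labeled_scan_set")
  stopifnot(sum(ds$y == 1) == sum(ds$y == -1))
  ds
}

#' @export
print.labeled_scan_set <- function(x, ...) {
  cat(sprintf("<labeled_scan_set> %d scans x %d features (%d per class, %d runs)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), length(unique(x$run_id))))
  invisible(x)
}

subset_scan_set <- function(ds, i) {
  structure(list(X = ds$X[i, , drop = FALSE], y = ds$y[i],
                 block_id = ds$block_id[i], run_id = ds$run_id[i],
                 mask_ref = ds$mask_ref), class = "labeled_scan_set")
}

#' Min-max feature scaling to [-1, 1]
#'
#' Per feature, `x -> 2 (x - min) / (max - min) - 1` with min/max taken
#' from the training data only; the identical affine map is applied to any
#' other data, whose values may fall outside `[-1, 1]` (no clipping). A
#' constant training feature maps to 0 everywhere.
#'
#' @param train_X training matrix (scans x features).
#' @param other_X optional matrix scaled with the training parameters.
#' @return List with `train`, `other` (or NULL), and `scaler`
#'   (`list(min, max)`).
#' @export
minmax_scale <- function(train_X, other_X = NULL) {
  mn <- apply(train_X, 2, min)
  mx <- apply(train_X, 2, max)
  scaler <- list(min = mn, max = mx)
  list(train = apply_scaler(scaler, train_X),
       other = if (!is.null(other_X)) apply_scaler(scaler, other_X),
       scaler = scaler)
}

#' @rdname minmax_scale
#' @param scaler a scaler from [minmax_scale()].
#' @param X matrix to scale.
#' @export
apply_scaler <- function(scaler, X) {
  rng <- scaler$max - scaler$min
  const <- rng <= 0
  rng[const] <- 1
  S <- sweep(sweep(X, 2, scaler$min), 2, rng / 2, "/") - 1
  S[, const] <- 0
  S
}

# fit the soft-margin linear classifier on ALREADY-SCALED data; returns
# (w, b) oriented so that f(x) = w.x + b > 0 predicts class +1
svm_fit_scaled <- function(Xs, y, cfg) {
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = cfg$C, scale = FALSE,
                    tolerance = cfg$tolerance)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # LIBSVM orients the decision function toward the first class it meets in
  # the data; normalize to "+1 is positive" by checking agreement
  pred <- predict(fit, Xs)
  f <- as.numeric(Xs %*% w + b)
  agree <- mean((f > 0) == (pred == "pos"))
  if (agree < 0.5) { w <- -w; b <- -b }
  list(w = w, b = b)
}

#' Train the single-scan classifier
#'
#' Fits the min-max scaler on the training scans, then trains the linear
#' soft-margin classifier (C as in `cfg`). The positive class (+1) is
#' TASK_A / "yes".
#'
#' @param dataset a `labeled_scan_set`.
#' @param cfg an [svm_config()].
#' @return Object of class `scan_classifier` with `w`, `b`, `scaler`,
#'   `config`, `mask_ref`.
#' @export
train_classifier <- function(dataset, cfg = svm_config()) {
  if (length(unique(dataset$y)) < 2)
    stop_config("training data must contain both classes")
  sc <- minmax_scale(dataset$X)
  wb <- svm_fit_scaled(sc$train, dataset$y, cfg)
  structure(list(w = wb$w, b = wb$b, scaler = sc$scaler, config = cfg,
                 mask_ref = dataset$mask_ref),
            class = "scan_classifier")
}

#' Classify scans with a trained classifier
#'
#' Applies the stored training scaler, then the linear decision function.
#' A decision value of exactly 0 is labeled +1 (deterministic tie rule).
#'
#' @param model a `scan_classifier`.
#' @param X raw (unscaled) scans x features matrix.
#' @return List with `values` (decision values) and `labels` (+1 / -1).
#' @export
predict_scans <- function(model, X) {
  Xs <- apply_scaler(model$scaler, X)
  v <- as.numeric(Xs %*% model$w + model$b)
  list(values = v, labels = ifelse(v >= 0, 1, -1))
}

#' @export
print.scan_classifier <- function(x, ...) {
  cat(sprintf("<scan_classifier> linear, C = %g, %d features (%s mask)\n",
              x$config$C, length(x$w), x$mask_ref$kind))
  invisible(x)
}

#' Leave-one-run-out cross-validation
#'
#' Each run serves once as the held-out test set; the classifier (including
#' its feature scaler) is fitted on the remaining runs only. The pooled
#' accuracy divides the correctly classified scans accumulated over all
#' folds by the total number of valid scans, i.e. it is the scan-count
#' weighted mean of fold accuracies.
#'
#' @param dataset a `labeled_scan_set` spanning at least 2 runs.
#' @param cfg an [svm_config()].
#' @return List with `folds` (data frame: run, n, correct, accuracy) and
#'   `pooled_accuracy`.
#' @export
loro_cv <- function(dataset, cfg = svm_config()) {
  runs <- sort(unique(dataset$run_id))
  if (length(runs) < 2)
    stop_config("leave-one-run-out needs at least 2 runs")
  folds <- lapply(runs, function(r) {
    test <- dataset$run_id == r
    model <- train_classifier(subset_scan_set(dataset, !test), cfg)
    pred <- predict_scans(model, dataset$X[test, , drop = FALSE])
    data.frame(run = r, n = sum(test),
               correct = sum(pred$labels == dataset$y[test]))
  })
  folds <- do.call(rbind, folds)
  folds$accuracy <- folds$correct / folds$n
  list(folds = folds,
       pooled_accuracy = sum(folds$correct) / sum(folds$n))
}

# one balanced-block permutation of the labels: within each run, the
# multiset of block labels is randomly reassigned across that run's blocks;
# every scan inherits its block's permuted label
permute_block_labels <- function(dataset) {
  y <- dataset$y
  for (r in unique(dataset$run_id)) {
    in_run <- dataset$run_id == r
    blocks <- unique(dataset$block_id[in_run])
    lab <- vapply(blocks, function(b)
      dataset$y[match(b, dataset$block_id)], 0)
    new_lab <- lab[sample.int(length(lab))]
    for (j in seq_along(blocks))
      y[dataset$block_id == blocks[j]] <- new_lab[j]
  }
  y
}

#' Balanced-block permutation test of classification accuracy
#'
#' Builds the null distribution of accuracy by re-training the classifier
#' under label permutations that respect the paradigm's block structure:
#' labels are reassigned at block granularity, independently within each
#' run, by permuting the run's multiset of block labels across its blocks.
#' This preserves run structure, block structure (hence the temporal
#' autocorrelation of within-block scans), and per-run class balance. The
#' feature scaler depends on the data only, not the labels, so it is fitted
#' once. The p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @param dataset the training `labeled_scan_set`.
#' @param eval_X,eval_y held-out evaluation scans (raw) and their true
#'   labels; typically the response-period scans of the binary-answer runs.
#' @param cfg an [svm_config()].
#' @param n_permutations number of label permutations (the study default
#'   is 5000).
#' @param seed integer RNG seed.
#' @return Object of class `permutation_result` with `observed_accuracy`,
#'   `null_accuracies`, `p_value`, `n_permutations`, `seed`.
#' @export
balanced_block_permutation_test <- function(dataset, eval_X, eval_y,
                                            cfg = svm_config(),
                                            n_permutations = 5000,
                                            seed = 1L) {
  if (n_permutations < 1) stop_config("n_permutations must be >= 1")
  model <- train_classifier(dataset, cfg)
  obs <- mean(predict_scans(model, eval_X)$labels == eval_y)
  Xs <- apply_scaler(model$scaler, dataset$X)
  Es <- apply_scaler(model$scaler, eval_X)
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      yp <- permute_block_labels(dataset)
      wb <- svm_fit_scaled(Xs, yp, cfg)
      v <- as.numeric(Es %*% wb$w + wb$b)
      mean(ifelse(v >= 0, 1, -1) == eval_y)
    }, 0)
  })
  p <- (1 + sum(null_acc >= obs)) / (1 + n_permutations)
  structure(list(observed_accuracy = obs, null_accuracies = null_acc,
                 p_value = p, n_permutations = n_permutations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed accuracy %.3f, ",
                     "null mean %.3f, p = %.4g (%d permutations)\n"),
              x$observed_accuracy, mean(x$null_accuracies), x$p_value,
              x$n_permutations))
  invisible(x)
}
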