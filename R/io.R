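# On-disk interchange: runs as NIfTI + events/confounds TSV + JSON sidecar,
# feature masks as NIfTI + JSON, classifiers and reports as JSON. Every
# pipeline stage can be re-run from these files.

nifti_with_grid <- function(arr, voxel_size_mm, tr = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (is.null(tr)) voxel_size_mm else c(voxel_size_mm, tr)
  RNifti::pixdim(img) <- pd
  img
}

#' Write / read a BOLD run
#'
#' Writes `<prefix>_bold.nii.gz`, `<prefix>_events.tsv`,
#' `<prefix>_confounds.tsv`, and `<prefix>_meta.json` (acquisition
#' parameters, run identity, provenance). `read_bold_run` reconstructs the
#' full `bold_run`, rebuilding the schedule from the events table.
#'
#' @param run a `bold_run`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. `"run-01"`.
#' @param brain_mask logical 3D array; stored once per dataset, so it must
#'   be supplied when reading a single run.
#' @return `write_bold_run` returns the prefix path invisibly;
#'   `read_bold_run` returns a `bold_run`.
#' @export
write_bold_run <- function(run, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- run$schedule$acquisition
  RNifti::writeNifti(nifti_with_grid(run$data, acq$voxel_size_mm,
                                     acq$tr_seconds),
                     file.path(dir, paste0(prefix, "_bold.nii.gz")))
  write_events(run$schedule, file.path(dir, paste0(prefix, "_events.tsv")))
  utils::write.table(run$confounds,
                     file.path(dir, paste0(prefix, "_confounds.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(run_id = run$schedule$run_id, day = run$schedule$day,
               kind = run$schedule$kind,
               acq = unclass(acq),
               n_dummy_dropped = run$n_dummy_dropped,
               provenance = run$provenance)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, prefix))
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(dir, prefix, brain_mask) {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  acq <- acq_params(meta$acq$tr_seconds, meta$acq$n_dummy_scans,
                    meta$acq$grid_shape, meta$acq$voxel_size_mm)
  ev <- read_events(file.path(dir, paste0(prefix, "_events.tsv")))
  trials <- NULL
  if (meta$kind == "BINARY_ANSWER") {
    sent <- ev[ev$trial_type == "SENTENCE", , drop = FALSE]
    resp <- ev[ev$trial_type == "RESPONSE", , drop = FALSE]
    trials <- data.frame(sentence_id = seq_len(nrow(resp)),
                         sentence_onset_seconds = sent$onset,
                         prompt_onset_seconds = resp$onset,
                         response_duration_seconds = resp$duration,
                         true_answer = resp$true_answer,
                         stringsAsFactors = FALSE)
  }
  sched <- new_run_schedule(meta$run_id, meta$day, meta$kind, acq,
                            ev[, c("onset", "duration", "trial_type",
                                   "acknowledged")], trials)
  voxels <- as.numeric(
    RNifti::readNifti(file.path(dir, paste0(prefix, "_bold.nii.gz"))))
  data <- array(voxels,
                dim = c(acq$grid_shape,
                        length(voxels) %/% prod(acq$grid_shape)))
  conf <- utils::read.table(file.path(dir, paste0(prefix, "_confounds.tsv")),
                            header = TRUE, sep = "\t")
  nd <- meta$n_dummy_dropped %||% 0L
  structure(list(data = data, schedule = sched, confounds = conf,
                 brain_mask = brain_mask,
                 n_dummy_dropped = as.integer(nd),
                 provenance = meta$provenance),
            class = "bold_run")
}

#' Write / read a simulated experiment directory
#'
#' Layout: `day1/`, `day2_alt/`, `day2_binary/` run files, ground-truth
#' volumes (`truth_brain_mask.nii.gz`, `truth_beta_a.nii.gz`,
#' `truth_beta_b.nii.gz`), and `dataset.json`.
#'
#' @param experiment a `sim_experiment`.
#' @param dir dataset directory.
#' @return `write_experiment` returns `dir` invisibly; `read_experiment`
#'   returns a `sim_experiment`-shaped list (protocol fields limited to
#'   what downstream stages need).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c("day1", "day2_alt", "day2_binary")
  for (g in groups) {
    for (i in seq_along(experiment[[g]]))
      write_bold_run(experiment[[g]][[i]], file.path(dir, g),
                     sprintf("run-%02d", i))
  }
  tr <- experiment$truth
  vs <- tr$acq$voxel_size_mm
  RNifti::writeNifti(nifti_with_grid(tr$brain_mask + 0L, vs),
                     file.path(dir, "truth_brain_mask.nii.gz"))
  RNifti::writeNifti(nifti_with_grid(tr$beta_a, vs),
                     file.path(dir, "truth_beta_a.nii.gz"))
  RNifti::writeNifti(nifti_with_grid(tr$beta_b, vs),
                     file.path(dir, "truth_beta_b.nii.gz"))
  meta <- list(n_runs = lapply(groups, function(g) length(experiment[[g]])),
               seed = experiment$seed,
               answer_key = experiment$protocol$answer_key,
               baseline = experiment$truth$baseline)
  names(meta$n_runs) <- groups
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  mask_img <- RNifti::readNifti(file.path(dir, "truth_brain_mask.nii.gz"))
  brain_mask <- array(as.numeric(mask_img) > 0.5, dim = dim(mask_img))
  grp <- function(g) {
    n <- meta$n_runs[[g]]
    if (is.null(n) || n == 0) return(list())
    lapply(seq_len(n), function(i)
      read_bold_run(file.path(dir, g), sprintf("run-%02d", i), brain_mask))
  }
  rd_beta <- function(f) {
    img <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(img), dim = dim(img))
  }
  acq <- NULL
  day1 <- grp("day1"); day2_alt <- grp("day2_alt")
  day2_binary <- grp("day2_binary")
  first <- c(day1, day2_alt, day2_binary)[[1]]
  truth <- structure(list(beta_a = rd_beta("truth_beta_a.nii.gz"),
                          beta_b = rd_beta("truth_beta_b.nii.gz"),
                          brain_mask = brain_mask,
                          baseline = meta$baseline,
                          acq = first$schedule$acquisition),
                     class = "ground_truth")
  structure(list(day1 = day1, day2_alt = day2_alt,
                 day2_binary = day2_binary, truth = truth,
                 protocol = list(answer_key = meta$answer_key),
                 seed = meta$seed),
            class = "sim_experiment")
}

#' Write / read a feature mask
#'
#' Binary NIfTI volume plus a JSON sidecar recording the threshold kind,
#' degrees of freedom, t cutoff, source runs and voxel count.
#'
#' @param mask a `feature_mask`.
#' @param path output path without extension; `.nii.gz` and `.json` are
#'   appended.
#' @param voxel_size_mm voxel sizes for the NIfTI header.
#' @return `write_feature_mask` returns `path` invisibly;
#'   `read_feature_mask` returns a `feature_mask`.
#' @export
write_feature_mask <- function(mask, path, voxel_size_mm = c(3, 3, 5)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(nifti_with_grid(mask$mask + 0L, voxel_size_mm),
                     paste0(path, ".nii.gz"))
  jsonlite::write_json(
    list(threshold_kind = mask$threshold_kind,
         source_runs = mask$source_runs, n_voxels = mask$n_voxels,
         t_cutoff = mask$t_cutoff, dof = mask$dof),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_mask
#' @export
read_feature_mask <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_mask(array(as.numeric(img) > 0.5, dim = dim(img)),
               side$threshold_kind,
               source_runs = side$source_runs %||% integer(),
               t_cutoff = side$t_cutoff %||% NA_real_,
               dof = side$dof %||% NA_real_)
}

#' Write / read a trained classifier
#'
#' Single JSON archive holding the weight vector, bias, per-feature scaler,
#' configuration, and feature-mask reference (grid + voxel indices).
#'
#' @param model a `scan_classifier`.
#' @param path output `.json` path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns a `scan_classifier`.
#' @export
write_classifier <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(w = model$w, b = model$b,
         scaler = model$scaler,
         config = unclass(model$config),
         mask_ref = model$mask_ref),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = obj$w, b = obj$b,
                 scaler = list(min = obj$scaler$min, max = obj$scaler$max),
                 config = structure(obj$config, class = "svm_config"),
                 mask_ref = list(voxels = obj$mask_ref$voxels,
                                 grid = obj$mask_ref$grid,
                                 kind = obj$mask_ref$kind)),
            class = "scan_classifier")
}
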