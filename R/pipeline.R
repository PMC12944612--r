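#' Pipeline run configuration
#'
#' Collects every tunable pipeline constant with its standard default:
#' 250 Hz sampling, 30 s epochs, 0.5-50 Hz second-order Butterworth
#' band-pass (zero-phase by default), per-epoch IAF anchoring, hidden
#' sizes 5-25 in steps of 5, 10-fold cross-validation. Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @param config_file Optional YAML file of overrides; explicit \code{...}
#'   arguments win over file values.
#' @return A named \code{run_config} list.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(
    sample_rate = 250, epoch_seconds = 30,
    filter_low_hz = 0.5, filter_high_hz = 50, filter_order = 2,
    filter_mode = "zero_phase",
    iaf_mode = "per_epoch",
    hidden_sizes = c(5L, 10L, 15L, 20L, 25L),
    k_folds = 10L, seed = 1L,
    input_format = "csv"
  )
  file_over <- if (!is.null(config_file)) {
    yaml::read_yaml(config_file)
  } else list()
  flag_over <- list(...)
  merged <- utils::modifyList(utils::modifyList(defaults, file_over), flag_over)
  unknown <- setdiff(names(merged), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!merged$filter_mode %in% c("zero_phase", "causal")) {
    stop("filter_mode must be 'zero_phase' or 'causal'", call. = FALSE)
  }
  if (!merged$iaf_mode %in% c("per_epoch", "subject_mean")) {
    stop("iaf_mode must be 'per_epoch' or 'subject_mean'", call. = FALSE)
  }
  if (!merged$input_format %in% c("csv", "edf")) {
    stop("input_format must be 'csv' or 'edf'", call. = FALSE)
  }
  structure(merged, class = "run_config")
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[drowseeg] ", fmt), ...))
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one recording CSV and one hypnogram per subject plus a
#' manifest CSV of the true generator parameters.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_subjects,epochs_per_state Cohort shape.
#' @param noise_fraction Alpha-band noise-to-tone power fraction
#'   (see [default_cohort_spec()]).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = run_config(), out_dir,
                         n_subjects = 10, epochs_per_state = 20,
                         noise_fraction = 0.1) {
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- default_cohort_spec(
    n_subjects = n_subjects, n_wake_epochs = epochs_per_state,
    n_s1_epochs = epochs_per_state, noise_fraction = noise_fraction,
    seed = config$seed, sample_rate = config$sample_rate,
    epoch_seconds = config$epoch_seconds
  )
  cohort <- generate_cohort(spec)
  paths <- list()
  for (id in names(cohort$recordings)) {
    rec_path <- file.path(out_dir, paste0(id, "_recording.csv"))
    hyp_path <- file.path(out_dir, paste0(id, "_hypnogram.txt"))
    write_recording_csv(cohort$recordings[[id]], rec_path)
    write_hypnogram(cohort$hypnograms[[id]], hyp_path)
    paths[[id]] <- c(recording = rec_path, hypnogram = hyp_path)
  }
  manifest <- do.call(rbind, lapply(spec$subjects, function(s) {
    data.frame(subject_id = s$subject_id, iaf_true = s$iaf_true,
               alpha_amp_wake = s$alpha_amp_wake,
               alpha_atten_s1 = s$alpha_atten_s1,
               slow_amp_wake = s$slow_amp_wake, slow_amp_s1 = s$slow_amp_s1,
               noise_amp = s$noise_amp,
               n_wake_epochs = s$n_wake_epochs, n_s1_epochs = s$n_s1_epochs)
  }))
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  pipeline_log("simulated %d subjects (seed %d) into %s",
               n_subjects, config$seed, out_dir)
  invisible(c(paths, list(manifest = manifest_path)))
}

extract_one <- function(recording, hyp, config) {
  filtered <- bandpass(recording, config$filter_low_hz, config$filter_high_hz,
                       config$filter_order, mode = config$filter_mode)
  es <- segment(filtered, hyp)
  res <- extract_features(es, iaf_mode = config$iaf_mode)
  pipeline_log("subject %s: %d epochs, anchor IAF %.3f Hz (%s)",
               res$anchors$subject_id, nrow(res$features),
               res$anchors$iaf_hz, res$anchors$iaf_source)
  res
}

#' Extract features from recordings on disk
#'
#' Runs filter, segmentation and feature extraction for each
#' recording/hypnogram pair and writes one combined feature-table CSV
#' plus a per-subject anchors CSV next to it.
#'
#' @param config A [run_config()].
#' @param recording_paths,hypnogram_paths Parallel path vectors.
#' @param out Path of the feature-table CSV to write.
#' @return Invisibly, the combined feature data frame.
#' @export
run_extract <- function(config = run_config(), recording_paths, hypnogram_paths,
                        out) {
  stopifnot(length(recording_paths) == length(hypnogram_paths),
            length(recording_paths) >= 1)
  results <- lapply(seq_along(recording_paths), function(i) {
    rec <- switch(config$input_format,
      csv = read_recording_csv(recording_paths[i]),
      edf = read_recording_edf(recording_paths[i], channel = "C3-O1")
    )
    hyp <- read_hypnogram(hypnogram_paths[i], config$epoch_seconds)
    tryCatch(extract_one(rec, hyp, config), error = function(e) {
      stop(sprintf("subject %s (%s): %s", rec$subject_id, recording_paths[i],
                   conditionMessage(e)), call. = FALSE)
    })
  })
  features <- do.call(rbind, lapply(results, `[[`, "features"))
  anchors <- do.call(rbind, lapply(results, `[[`, "anchors"))
  write_feature_table(features, out)
  utils::write.csv(anchors, sub("\\.csv$", "_anchors.csv", out),
                   row.names = FALSE, quote = FALSE)
  invisible(features)
}

#' Cross-validate every subject in a feature table
#'
#' Runs per-subject stratified k-fold cross-validation (with the
#' hidden-size sweep inside each training fold) and a cohort summary.
#' Per-subject report CSVs and a cohort summary CSV are written when
#' \code{out_dir} is given.
#'
#' @param config A [run_config()].
#' @param features Feature data frame or path to a feature-table CSV.
#' @param out_dir Optional output directory for report files.
#' @return List with \code{reports} (per subject) and \code{summary}.
#' @export
run_evaluate <- function(config = run_config(), features, out_dir = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  subjects <- unique(features$subject_id)
  reports <- lapply(subjects, function(id) {
    rows <- features[features$subject_id == id, , drop = FALSE]
    rep_ <- kfold(rows, k = config$k_folds, seed = config$seed,
                  hidden_sizes = config$hidden_sizes)
    pipeline_log("subject %s: pooled accuracy %.2f%% (TPR %.2f%%, TNR %.2f%%)",
                 id, rep_$pooled_metrics$accuracy, rep_$pooled_metrics$tpr,
                 rep_$pooled_metrics$tnr)
    rep_
  })
  summary <- cohort_summary(reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in reports) {
      write_eval_report(r, file.path(out_dir, paste0(r$subject_id, "_cv.csv")))
    }
    utils::write.csv(summary$per_subject, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  pipeline_log("cohort means: TPR %.2f%%, TNR %.2f%%, accuracy %.2f%%",
               summary$mean_tpr, summary$mean_tnr, summary$mean_accuracy)
  list(reports = reports, summary = summary)
}

#' Apply a saved model to a recording, epoch by epoch
#'
#' The offline stand-in for the online alerting loop: filters the
#' recording, cuts it into consecutive epochs (a trailing partial epoch
#' is ignored with a warning), extracts features and emits one
#' (epoch_index, label, score) row per epoch.
#'
#' @param config A [run_config()].
#' @param model_file Path to a [save_model()] file.
#' @param recording An [eeg_recording()] or a path to one (per
#'   \code{config$input_format}).
#' @return Data frame with \code{epoch_index}, \code{label}, \code{score}.
#' @export
run_detect <- function(config = run_config(), model_file, recording) {
  model <- load_model(model_file)
  if (is.character(recording)) {
    recording <- switch(config$input_format,
      csv = read_recording_csv(recording),
      edf = read_recording_edf(recording, channel = "C3-O1")
    )
  }
  n_per <- as.integer(round(config$sample_rate * config$epoch_seconds))
  n_full <- length(recording$samples) %/% n_per
  if (n_full < 1) stop("recording shorter than one epoch", call. = FALSE)
  if (n_full * n_per < length(recording$samples)) {
    warning(sprintf("ignoring %d trailing samples (partial epoch)",
                    length(recording$samples) - n_full * n_per))
  }
  # an all-W pseudo-hypnogram keeps every full epoch; labels are discarded
  hyp <- hypnogram(rep("W", n_full), config$epoch_seconds)
  filtered <- bandpass(recording, config$filter_low_hz, config$filter_high_hz,
                       config$filter_order, mode = config$filter_mode)
  es <- segment(filtered, hyp)
  feats <- extract_features(es, iaf_mode = config$iaf_mode)$features
  pred <- predict_drowsiness(model, feats)
  data.frame(epoch_index = feats$epoch_index, label = pred$label,
             score = pred$score, stringsAsFactors = FALSE)
}
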