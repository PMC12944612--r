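#' Single-channel EEG recording
#'
#' @param subject_id Subject label.
#' @param samples Numeric sample vector (non-empty, finite).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel Channel label, e.g. \code{"C3-O1"}.
#' @return An \code{eeg_recording} object.
#' @export
eeg_recording <- function(subject_id, samples, sample_rate, channel = "C3-O1") {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  stop_if_not_finite(samples, "samples")
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be > 0", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, samples = as.numeric(samples),
         sample_rate = sample_rate, channel = channel),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Hypnogram (per-epoch sleep-stage labels)
#'
#' Labels use the fixed alphabet \code{W} (wake), \code{S1} (stage-1
#' sleep) and \code{OTHER} (any other stage); label i covers samples
#' \code{[i*N, (i+1)*N)} of the aligned recording (0-based, half-open).
#'
#' @param labels Character vector of stage labels.
#' @param epoch_seconds Duration covered by each label (default 30).
#' @return A \code{hypnogram} object.
#' @export
hypnogram <- function(labels, epoch_seconds = 30) {
  if (length(labels) == 0) stop("hypnogram labels must be non-empty", call. = FALSE)
  if (epoch_seconds <= 0) stop("epoch_seconds must be > 0", call. = FALSE)
  bad <- setdiff(unique(labels), c("W", "S1", "OTHER"))
  if (length(bad)) {
    stop(sprintf("unknown stage label(s): %s (use normalize_stage_labels())",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = as.character(labels), epoch_seconds = epoch_seconds),
            class = "hypnogram")
}

#' Normalize raw stage labels to the W/S1/OTHER alphabet
#'
#' Recognized aliases cover Rechtschaffen-Kales ("S1"), AASM ("N1") and
#' numeric sleep-database codes: \code{W}, \code{w}, \code{0} map to
#' \code{W}; \code{1}, \code{S1}, \code{N1} map to \code{S1}; everything
#' else maps to \code{OTHER}.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector over \code{{W, S1, OTHER}}.
#' @export
normalize_stage_labels <- function(raw) {
  raw <- trimws(as.character(raw))
  out <- rep("OTHER", length(raw))
  out[raw %in% c("W", "w", "0")] <- "W"
  out[raw %in% c("1", "S1", "N1")] <- "S1"
  out
}

#' Read / write the recording CSV dialect
#'
#' The fixture format is a plain text file whose first line holds the
#' three metadata values \code{subject_id,channel,sample_rate} and whose
#' remaining lines hold one sample value each.
#'
#' @param path File path.
#' @return [read_recording_csv()] returns an [eeg_recording()].
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) {
    stop(sprintf("%s: expected a metadata line plus at least one sample line", path),
         call. = FALSE)
  }
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L) {
    stop(sprintf("%s line 1: malformed header, expected 'subject_id,channel,sample_rate'",
                 path), call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(hdr[3L]))
  if (!is.finite(rate) || rate <= 0) {
    stop(sprintf("%s line 1: sample_rate '%s' is not a positive number", path, hdr[3L]),
         call. = FALSE)
  }
  body <- lines[-1L]
  samples <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(samples))
  if (length(bad)) {
    stop(sprintf("%s line %d: cannot parse sample value '%s'",
                 path, bad[1L] + 1L, body[bad[1L]]), call. = FALSE)
  }
  eeg_recording(subject_id = trimws(hdr[1L]), samples = samples,
                sample_rate = rate, channel = trimws(hdr[2L]))
}

#' @param recording An [eeg_recording()].
#' @rdname read_recording_csv
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s,%s,%s", recording$subject_id, recording$channel,
                     format(recording$sample_rate, digits = 15)), con)
  writeLines(format(recording$samples, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' Read / write hypnogram text files
#'
#' One raw stage label per line; labels are normalized through
#' [normalize_stage_labels()] on read.
#'
#' @param path File path.
#' @param epoch_seconds Seconds per label (default 30).
#' @return [read_hypnogram()] returns a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_seconds = 30) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop(sprintf("%s: empty hypnogram file", path), call. = FALSE)
  }
  hypnogram(normalize_stage_labels(lines), epoch_seconds)
}

#' @param hyp A [hypnogram()].
#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(hyp$labels, path)
  invisible(path)
}

feature_table_cols <- c("subject_id", "epoch_index", "label",
                        "p_iaf", "p_tf", "p_3hz", "p_4hz", "ratio_r")

#' Read / write the per-epoch feature table
#'
#' CSV with fixed column order \code{subject_id, epoch_index, label,
#' p_iaf, p_tf, p_3hz, p_4hz, ratio_r}; labels are \code{alert} or
#' \code{drowsy}. Reading a written table reproduces it within float
#' round-trip precision.
#'
#' @param table Data frame with the feature-table columns.
#' @param path File path.
#' @return [read_feature_table()] returns the feature data frame.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(feature_table_cols, names(table))
  if (length(missing_cols)) {
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(
    format(table[feature_table_cols], digits = 17, trim = TRUE, scientific = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(feature_table_cols, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: not a feature table (missing %s)", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab <- tab[feature_table_cols]
  if (nrow(tab) == 0) return(tab)
  bad <- setdiff(unique(tab$label), c("alert", "drowsy"))
  if (length(bad)) {
    stop(sprintf("%s: unknown label(s) %s (expected alert/drowsy)", path,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  num_cols <- c("p_iaf", "p_tf", "p_3hz", "p_4hz", "ratio_r")
  for (cl in num_cols) {
    if (any(!is.finite(tab[[cl]])) || any(tab[[cl]] < 0)) {
      stop(sprintf("%s: column %s contains non-finite or negative values", path, cl),
           call. = FALSE)
    }
  }
  tab
}
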