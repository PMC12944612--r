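#' Band-pass filter a recording
#'
#' Second-order Butterworth band-pass (default 0.5-50 Hz), applied
#' zero-phase (forward-backward, \code{signal::filtfilt}) by default so
#' that epoch boundaries are not smeared by group delay. A causal
#' single-pass mode is available for streaming parity. Note that
#' forward-backward application squares the magnitude response, i.e.
#' doubles the effective order.
#'
#' @param recording An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz (defaults 0.5 and 50).
#' @param order Butterworth order (default 2).
#' @param mode \code{"zero_phase"} (default) or \code{"causal"}.
#' @return The filtered [eeg_recording()], same length.
#' @export
bandpass <- function(recording, low_hz = 0.5, high_hz = 50, order = 2,
                     mode = c("zero_phase", "causal")) {
  stopifnot(inherits(recording, "eeg_recording"))
  mode <- match.arg(mode)
  nyq <- recording$sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("band edges must satisfy 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq), call. = FALSE)
  }
  bw <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- recording$samples
  y <- if (mode == "zero_phase") {
    signal::filtfilt(bw, x)
  } else {
    as.numeric(signal::filter(bw, x))
  }
  out <- recording
  out$samples <- y
  out
}

#' Segment a recording into labeled epochs
#'
#' Cuts the recording on the hypnogram's 30 s grid (epoch i covers
#' samples \code{[i*N, (i+1)*N)}), keeps only wake and stage-1 epochs and
#' maps their stage labels to classifier classes: \code{W} becomes
#' \code{alert}, \code{S1} becomes \code{drowsy} (drowsy is the positive
#' class throughout). Epochs labeled \code{OTHER} are dropped, a trailing
#' partial epoch is discarded, and hypnogram labels beyond the end of the
#' recording are ignored with a warning.
#'
#' @param recording An [eeg_recording()].
#' @param hyp A [hypnogram()] aligned to the recording from sample 0.
#' @return An \code{epoch_set}: list with \code{epochs} (list of
#'   length-N sample vectors), \code{labels} (\code{alert}/\code{drowsy}),
#'   \code{sample_rate}, \code{epoch_seconds}, \code{subject_id}.
#' @export
segment <- function(recording, hyp) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(hyp, "hypnogram"))
  n_per <- recording$sample_rate * hyp$epoch_seconds
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("sample_rate * epoch_seconds must be an integer number of samples",
         call. = FALSE)
  }
  n_per <- as.integer(round(n_per))
  n_full <- length(recording$samples) %/% n_per
  labels <- hyp$labels
  if (length(labels) > n_full) {
    warning(sprintf("subject %s: hypnogram has %d labels but recording holds %d full epochs; ignoring the excess",
                    recording$subject_id, length(labels), n_full))
    labels <- labels[seq_len(n_full)]
  }
  keep <- which(labels %in% c("W", "S1"))
  if (length(keep) == 0) {
    stop(sprintf("subject %s: no W/S1 epochs to analyze", recording$subject_id),
         call. = FALSE)
  }
  epochs <- lapply(keep, function(i) {
    recording$samples[((i - 1L) * n_per + 1L):(i * n_per)]
  })
  structure(
    list(
      epochs = epochs,
      labels = ifelse(labels[keep] == "W", "alert", "drowsy"),
      epoch_index = keep - 1L,
      sample_rate = recording$sample_rate,
      epoch_seconds = hyp$epoch_seconds,
      subject_id = recording$subject_id
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> subject %s: %d epochs (%d alert, %d drowsy) of %g s @ %g Hz\n",
              x$subject_id, length(x$epochs), sum(x$labels == "alert"),
              sum(x$labels == "drowsy"), x$epoch_seconds, x$sample_rate))
  invisible(x)
}
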