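# Bins whose physical frequency lies in [lo, hi] (inclusive both ends),
# as 0-based indices into the exposed half-spectrum.
band_bins <- function(p, lo, hi) {
  k_lo <- ceiling(lo * p$n_samples / p$sample_rate - 1e-9)
  k_hi <- floor(hi * p$n_samples / p$sample_rate + 1e-9)
  k_hi <- min(k_hi, length(p$power) - 1L)
  if (k_lo > k_hi) return(integer(0))
  as.integer(k_lo:k_hi)
}

#' Individual Alpha Frequency of a PSD
#'
#' The IAF is the frequency of maximum power within the alpha band,
#' fixed at 8-12 Hz (inclusive). Ties are broken toward the lowest
#' frequency. Alpha peak position varies across individuals (notably
#' with age), which is why the downstream features anchor on it instead
#' of on fixed band centers.
#'
#' @param p A [psd()] estimate covering 12 Hz.
#' @return IAF in Hz (a bin-center frequency in [8, 12]).
#' @export
find_iaf <- function(p) {
  stopifnot(inherits(p, "psd_estimate"))
  bins <- band_bins(p, 8, 12)
  if (length(bins) == 0) {
    stop("PSD has no bins in the 8-12 Hz alpha band (epoch too short or rate too low)",
         call. = FALSE)
  }
  pw <- p$power[bins + 1L]
  freq_of(bins[which.max(pw)], p$sample_rate, p$n_samples)
}

#' Theta anchor frequency
#'
#' The person-adaptive theta reference, defined as IAF minus 4 Hz, hence
#' in [4, 8] Hz.
#'
#' @param iaf_hz IAF in Hz, within [8, 12].
#' @return \code{iaf_hz - 4}.
#' @export
theta_frequency <- function(iaf_hz) {
  if (any(iaf_hz < 8) || any(iaf_hz > 12)) {
    stop("iaf_hz must lie in [8, 12] Hz", call. = FALSE)
  }
  iaf_hz - 4
}

#' Slow-to-alpha band power ratio
#'
#' Ratio of the average power over bins in 3-4 Hz to the average power
#' over bins in 8-12 Hz (both bands inclusive at both edges). Power
#' rises at 3-4 Hz and falls in the alpha band at sleep onset, so the
#' ratio increases from wake to stage-1 sleep.
#'
#' @param p A [psd()] estimate covering 12 Hz.
#' @return Non-negative ratio.
#' @export
band_power_ratio <- function(p) {
  stopifnot(inherits(p, "psd_estimate"))
  slow <- band_bins(p, 3, 4)
  alpha <- band_bins(p, 8, 12)
  if (length(slow) == 0 || length(alpha) == 0) {
    stop("PSD too coarse to cover the 3-4 Hz and 8-12 Hz bands", call. = FALSE)
  }
  denom <- mean(p$power[alpha + 1L])
  if (denom <= 0) {
    stop("degenerate alpha band: zero average alpha power in denominator",
         call. = FALSE)
  }
  mean(p$power[slow + 1L]) / denom
}

#' Extract the five-feature vector for every epoch
#'
#' For each epoch the Hanning-windowed PSD is computed and five features
#' are read off: power at the IAF, power at the theta frequency
#' (IAF - 4), power at 3 Hz, power at 4 Hz, and the slow-to-alpha band
#' power ratio. Single-frequency powers use nearest-bin lookup.
#'
#' Two anchoring modes are supported. With \code{iaf_mode = "per_epoch"}
#' (default) the IAF is located in each epoch's own spectrum; with
#' \code{"subject_mean"} it is located once in the mean PSD over the
#' subject's wake epochs (the alpha peak is a wake phenomenon) and then
#' held fixed for all epochs.
#'
#' @param epoch_set An [segment()] output.
#' @param iaf_mode \code{"per_epoch"} or \code{"subject_mean"}.
#' @return List with \code{features} (data frame: subject_id,
#'   epoch_index, label, p_iaf, p_tf, p_3hz, p_4hz, ratio_r, iaf_hz,
#'   tf_hz; ordered by epoch_index) and \code{anchors} (one-row data
#'   frame: subject_id, iaf_hz, tf_hz, iaf_source — the subject-level
#'   anchor; under per-epoch anchoring this is the median per-epoch wake
#'   IAF).
#' @export
extract_features <- function(epoch_set, iaf_mode = c("per_epoch", "subject_mean")) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  iaf_mode <- match.arg(iaf_mode)
  if (length(epoch_set$epochs) == 0) stop("empty epoch set", call. = FALSE)

  psds <- lapply(epoch_set$epochs, psd, sample_rate = epoch_set$sample_rate,
                 window = TRUE)

  if (iaf_mode == "subject_mean") {
    wake <- which(epoch_set$labels == "alert")
    ref <- if (length(wake)) wake else seq_along(psds)
    mean_psd <- psds[[ref[1]]]
    mean_psd$power <- rowMeans(vapply(psds[ref], function(p) p$power,
                                      numeric(length(mean_psd$power))))
    subj_iaf <- find_iaf(mean_psd)
  }

  rows <- lapply(seq_along(psds), function(i) {
    p <- psds[[i]]
    iaf <- if (iaf_mode == "per_epoch") find_iaf(p) else subj_iaf
    tf <- theta_frequency(iaf)
    lookup <- function(f) p$power[bin_of(f, p$sample_rate, p$n_samples) + 1L]
    data.frame(
      subject_id = epoch_set$subject_id,
      epoch_index = epoch_set$epoch_index[i],
      label = epoch_set$labels[i],
      p_iaf = lookup(iaf), p_tf = lookup(tf),
      p_3hz = lookup(3), p_4hz = lookup(4),
      ratio_r = band_power_ratio(p),
      iaf_hz = iaf, tf_hz = tf,
      stringsAsFactors = FALSE
    )
  })
  features <- do.call(rbind, rows)
  features <- features[order(features$epoch_index), , drop = FALSE]
  rownames(features) <- NULL

  anchor_iaf <- if (iaf_mode == "subject_mean") {
    subj_iaf
  } else {
    wake_iaf <- features$iaf_hz[features$label == "alert"]
    src <- if (length(wake_iaf)) wake_iaf else features$iaf_hz
    # median snapped to an observed value, so tf = iaf - 4 stays bin-exact
    sort(src)[ceiling(length(src) / 2)]
  }
  anchors <- data.frame(
    subject_id = epoch_set$subject_id,
    iaf_hz = anchor_iaf,
    tf_hz = theta_frequency(anchor_iaf),
    iaf_source = iaf_mode,
    stringsAsFactors = FALSE
  )
  list(features = features, anchors = anchors)
}
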