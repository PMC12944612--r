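#' Subject specification for the synthetic EEG generator
#'
#' Describes one simulated sleeper: an alpha oscillation at a
#' subject-specific Individual Alpha Frequency (IAF) riding on 1/f
#' background noise, plus slow (3 Hz and 4 Hz) components. During stage-1
#' sleep the alpha amplitude is attenuated and the slow components are
#' boosted, which is the spectral transition the detection method relies
#' on: alpha power collapses and 3-4 Hz power rises at sleep onset.
#'
#' @param subject_id Subject label.
#' @param iaf_true True alpha peak frequency in Hz, within [8, 12].
#' @param alpha_amp_wake Alpha tone amplitude during wake (> 0).
#' @param alpha_atten_s1 Multiplicative alpha attenuation in S1, in [0, 1).
#' @param slow_amp_wake Amplitude of the 3 Hz and 4 Hz tones during wake (>= 0).
#' @param slow_amp_s1 Amplitude of the slow tones during S1
#'   (must exceed \code{slow_amp_wake}).
#' @param noise_amp Standard deviation of the 1/f background noise (>= 0).
#' @param n_wake_epochs,n_s1_epochs Epoch counts per state (non-negative,
#'   at least one epoch in total).
#' @return A \code{subject_spec} list.
#' @export
subject_spec <- function(subject_id, iaf_true, alpha_amp_wake = 1,
                         alpha_atten_s1 = 0.3, slow_amp_wake = 0.3,
                         slow_amp_s1 = 0.9, noise_amp = 0,
                         n_wake_epochs = 20, n_s1_epochs = 20) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L, nzchar(subject_id))
  if (!is.finite(iaf_true) || iaf_true < 8 || iaf_true > 12) {
    stop("iaf_true must lie in [8, 12] Hz", call. = FALSE)
  }
  if (alpha_amp_wake <= 0) stop("alpha_amp_wake must be > 0", call. = FALSE)
  if (alpha_atten_s1 < 0 || alpha_atten_s1 >= 1) {
    stop("alpha_atten_s1 must lie in [0, 1)", call. = FALSE)
  }
  if (slow_amp_wake < 0) stop("slow_amp_wake must be >= 0", call. = FALSE)
  if (slow_amp_s1 <= slow_amp_wake) {
    stop("slow_amp_s1 must exceed slow_amp_wake (slow power rises in S1)",
         call. = FALSE)
  }
  if (noise_amp < 0) stop("noise_amp must be >= 0", call. = FALSE)
  if (n_wake_epochs < 0 || n_s1_epochs < 0 ||
      n_wake_epochs != round(n_wake_epochs) || n_s1_epochs != round(n_s1_epochs)) {
    stop("epoch counts must be non-negative integers", call. = FALSE)
  }
  if (n_wake_epochs + n_s1_epochs < 1) {
    stop("at least one epoch is required", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, iaf_true = iaf_true,
         alpha_amp_wake = alpha_amp_wake, alpha_atten_s1 = alpha_atten_s1,
         slow_amp_wake = slow_amp_wake, slow_amp_s1 = slow_amp_s1,
         noise_amp = noise_amp,
         n_wake_epochs = as.integer(n_wake_epochs),
         n_s1_epochs = as.integer(n_s1_epochs)),
    class = "subject_spec"
  )
}

#' Cohort specification
#'
#' @param subjects List of [subject_spec()] objects.
#' @param sample_rate Sampling rate in Hz (default 250, the rate of the
#'   polysomnographic recordings the method targets).
#' @param epoch_seconds Epoch length in seconds (default 30, the standard
#'   sleep-scoring epoch).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(subjects, sample_rate = 250, epoch_seconds = 30, seed = 1L) {
  stopifnot(is.list(subjects), length(subjects) >= 1L)
  lapply(subjects, function(s) {
    if (!inherits(s, "subject_spec")) stop("subjects must be subject_spec objects", call. = FALSE)
  })
  if (sample_rate <= 100) {
    stop("sample_rate must exceed 100 Hz (Nyquist above the 50 Hz filter band)",
         call. = FALSE)
  }
  if (epoch_seconds <= 0) stop("epoch_seconds must be > 0", call. = FALSE)
  n <- sample_rate * epoch_seconds
  if (abs(n - round(n)) > 1e-9) {
    stop("sample_rate * epoch_seconds must be an integer number of samples",
         call. = FALSE)
  }
  structure(
    list(subjects = subjects, sample_rate = sample_rate,
         epoch_seconds = epoch_seconds, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# 1/f-shaped Gaussian noise: white noise shaped in the frequency domain with a
# 1/sqrt(f) magnitude envelope (DC bin zeroed), normalized to unit standard
# deviation. The envelope is symmetric in k and N-k so the output is real.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)
  env <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(stats::fft(w) * env, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic 30 s EEG epoch
#'
#' Draws random tone phases and background noise from the current RNG
#' state (seed upstream for reproducibility). The signal model is
#' additive: 1/f noise + an alpha sinusoid at \code{iaf_true} (attenuated
#' by \code{alpha_atten_s1} in state \code{"S1"}) + equal-amplitude 3 Hz
#' and 4 Hz sinusoids whose amplitude depends on the state. Each tone
#' gets an independent uniform random phase per epoch so epochs are
#' exchangeable within a state.
#'
#' @param spec A [subject_spec()].
#' @param state Stage label, \code{"W"} or \code{"S1"}.
#' @param sample_rate Sampling rate in Hz.
#' @param epoch_seconds Epoch duration in seconds.
#' @return Numeric vector of \code{sample_rate * epoch_seconds} samples.
#' @export
generate_epoch <- function(spec, state, sample_rate = 250, epoch_seconds = 30) {
  stopifnot(inherits(spec, "subject_spec"))
  if (!(is.character(state) && length(state) == 1L && state %in% c("W", "S1"))) {
    stop(sprintf("invalid state label '%s': must be 'W' or 'S1'",
                 paste(state, collapse = ",")), call. = FALSE)
  }
  n <- as.integer(round(sample_rate * epoch_seconds))
  t <- (seq_len(n) - 1L) / sample_rate
  alpha_amp <- spec$alpha_amp_wake * if (state == "S1") spec$alpha_atten_s1 else 1
  slow_amp <- if (state == "S1") spec$slow_amp_s1 else spec$slow_amp_wake
  # Fixed draw order (3 phases, then noise) keeps the RNG stream stable.
  ph <- stats::runif(3, 0, 2 * pi)
  sig <- alpha_amp * sin(2 * pi * spec$iaf_true * t + ph[1]) +
    slow_amp * sin(2 * pi * 3 * t + ph[2]) +
    slow_amp * sin(2 * pi * 4 * t + ph[3])
  if (spec$noise_amp > 0) sig <- sig + spec$noise_amp * pink_noise(n)
  sig
}

#' Generate a labeled synthetic cohort
#'
#' Produces one continuous recording plus an aligned hypnogram per
#' subject. Wake and S1 epochs are interleaved in a seeded-random order;
#' hypnogram label i covers samples \code{[i*N, (i+1)*N)} (0-based,
#' half-open). Identical seeds give bit-identical output.
#'
#' @param cohort A [cohort_spec()].
#' @return List with elements \code{recordings} (list of
#'   [eeg_recording()]) and \code{hypnograms} (list of [hypnogram()]),
#'   both named by subject id.
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  with_local_seed(cohort$seed, {
    recordings <- list()
    hypnograms <- list()
    for (spec in cohort$subjects) {
      labels <- c(rep("W", spec$n_wake_epochs), rep("S1", spec$n_s1_epochs))
      labels <- labels[sample.int(length(labels))]
      samples <- unlist(lapply(labels, function(st) {
        generate_epoch(spec, st, cohort$sample_rate, cohort$epoch_seconds)
      }), use.names = FALSE)
      recordings[[spec$subject_id]] <- eeg_recording(
        subject_id = spec$subject_id, samples = samples,
        sample_rate = cohort$sample_rate, channel = "C3-O1"
      )
      hypnograms[[spec$subject_id]] <- hypnogram(labels, cohort$epoch_seconds)
    }
    list(recordings = recordings, hypnograms = hypnograms)
  })
}

#' Calibrate the background-noise amplitude to a target alpha-band fraction
#'
#' Finds the \code{noise_amp} at which the 1/f background contributes a
#' given fraction of the wake alpha tone's power within the 8-12 Hz band.
#' Band-limited noise variance is measured spectrally (unwindowed
#' periodogram, Parseval scaling) on simulated unit-amplitude noise
#' epochs and compared with the tone power \eqn{A^2/2}; noise power
#' scales as \code{noise_amp^2}, so the calibrated amplitude is the
#' square root of the target-to-measured ratio. The measurement uses its
#' own fixed internal seed and is deterministic.
#'
#' @param alpha_amp Wake alpha tone amplitude.
#' @param target_fraction Desired alpha-band noise power as a fraction of
#'   tone power (default 0.1).
#' @param sample_rate,epoch_seconds Epoch geometry.
#' @param n_sim Number of noise epochs averaged in the measurement.
#' @return Calibrated noise amplitude (standard deviation units).
#' @export
calibrate_noise_amp <- function(alpha_amp = 1, target_fraction = 0.1,
                                sample_rate = 250, epoch_seconds = 30,
                                n_sim = 20) {
  stopifnot(target_fraction > 0, alpha_amp > 0)
  n <- as.integer(round(sample_rate * epoch_seconds))
  lo <- bin_of(8, sample_rate, n)
  hi <- bin_of(12, sample_rate, n)
  band_var <- with_local_seed(760501L, {
    mean(vapply(seq_len(n_sim), function(i) {
      p <- psd(pink_noise(n), sample_rate, window = FALSE)
      # two-sided band variance of the unit-sd noise
      2 * sum(p$power_full[(lo:hi) + 1L]) / n
    }, numeric(1)))
  })
  tone_power <- alpha_amp^2 / 2
  sqrt(target_fraction * tone_power / band_var)
}

#' Default 10-subject synthetic cohort
#'
#' The reference study conditions for the package's own experiments:
#' 10 subjects with true IAFs recycled over the grid 8.5, 9.0, ..., 11.5 Hz,
#' 20 wake + 20 S1 epochs each, alpha attenuated to 0.3 of its wake
#' amplitude in S1, slow-tone amplitude tripled in S1, and 1/f background
#' noise calibrated so its alpha-band power is 10% of the wake alpha tone
#' power (see [calibrate_noise_amp()]).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_wake_epochs,n_s1_epochs Epochs per state per subject (default 20).
#' @param noise_fraction Alpha-band noise-to-tone power fraction
#'   (default 0.1); set to 0 for noiseless cohorts.
#' @param seed Cohort seed.
#' @param sample_rate,epoch_seconds Epoch geometry (defaults 250 Hz, 30 s).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_subjects = 10, n_wake_epochs = 20,
                                n_s1_epochs = 20, noise_fraction = 0.1,
                                seed = 1L, sample_rate = 250,
                                epoch_seconds = 30) {
  stopifnot(n_subjects >= 1)
  iaf_grid <- rep(seq(8.5, 11.5, by = 0.5), length.out = n_subjects)
  noise_amp <- if (noise_fraction > 0) {
    calibrate_noise_amp(alpha_amp = 1, target_fraction = noise_fraction,
                        sample_rate = sample_rate, epoch_seconds = epoch_seconds)
  } else 0
  subjects <- lapply(seq_len(n_subjects), function(i) {
    subject_spec(
      subject_id = sprintf("s%02d", i), iaf_true = iaf_grid[i],
      alpha_amp_wake = 1, alpha_atten_s1 = 0.3,
      slow_amp_wake = 0.3, slow_amp_s1 = 0.9,
      noise_amp = noise_amp,
      n_wake_epochs = n_wake_epochs, n_s1_epochs = n_s1_epochs
    )
  })
  cohort_spec(subjects, sample_rate = sample_rate,
              epoch_seconds = epoch_seconds, seed = seed)
}
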