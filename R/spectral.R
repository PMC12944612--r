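#' Hanning window
#'
#' Symmetric Hanning taper \eqn{w(n) = \frac{1}{2}\left(1 - \cos\frac{2\pi n}{N-1}\right)},
#' \eqn{n = 0, \ldots, N-1}. Endpoints are exactly zero and the window is
#' symmetric about its midpoint; for odd \code{n} the midpoint value is
#' exactly 1.
#'
#' @param n Window length (integer, at least 2).
#' @return Numeric vector of length \code{n}.
#' @examples
#' hanning(5) # 0 0.5 1 0.5 0
#' @export
hanning <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2) {
    stop("hanning() requires an integer window length n >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  idx <- seq_len(n) - 1L
  0.5 * (1 - cos(2 * pi * idx / (n - 1L)))
}

#' Power spectral density of one epoch
#'
#' Computes the single-segment periodogram used throughout the pipeline:
#' the epoch is (optionally) multiplied by the symmetric Hanning window,
#' transformed by the FFT \eqn{X(k) = \sum_n Y(n) e^{-i 2\pi k n / N}},
#' and converted to power \eqn{PSD(k) = |X(k)|^2 / N}. No window
#' power-loss compensation is applied: downstream features are ratios and
#' within-convention comparisons, so the window constant cancels where it
#' matters. Absolute values are therefore not comparable with, e.g.,
#' Welch estimates.
#'
#' One whole-epoch FFT is taken per segment (no Welch averaging, no
#' zero-padding), so a 30 s epoch at 250 Hz has N = 7500 and a bin width
#' of 1/30 Hz.
#'
#' @param epoch Numeric sample vector (non-empty, finite).
#' @param sample_rate Sampling rate in Hz.
#' @param window Apply the Hanning window before the transform
#'   (default \code{TRUE}).
#' @return An object of class \code{psd_estimate} with fields
#'   \code{power} (bins 0..floor(N/2)), \code{power_full} (all N bins),
#'   \code{bin_width_hz}, \code{sample_rate} and \code{n_samples}.
#' @export
psd <- function(epoch, sample_rate, window = TRUE) {
  if (length(epoch) == 0) stop("epoch is empty", call. = FALSE)
  stop_if_not_finite(epoch, "epoch")
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number", call. = FALSE)
  }
  n <- length(epoch)
  y <- if (window && n >= 2) epoch * hanning(n) else epoch
  x <- stats::fft(y)
  pw <- Mod(x)^2 / n
  n_exposed <- floor(n / 2) + 1L
  structure(
    list(
      power = pw[seq_len(n_exposed)],
      power_full = pw,
      bin_width_hz = sample_rate / n,
      sample_rate = sample_rate,
      n_samples = n
    ),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> N = %d samples @ %g Hz, bin width %.6g Hz, %d exposed bins\n",
    x$n_samples, x$sample_rate, x$bin_width_hz, length(x$power)
  ))
  invisible(x)
}

#' Map a physical frequency to its FFT bin
#'
#' Nearest-bin mapping \code{k = round(f * N / sample_rate)} with exact
#' half-way ties rounded up, so that single-bin power lookups
#' \eqn{P(f) = PSD(k_f)} are deterministic.
#'
#' @param f_hz Frequency in Hz, between 0 and Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @param n Number of samples in the transform.
#' @return Integer bin index (0-based).
#' @seealso [freq_of()] for the inverse mapping.
#' @export
bin_of <- function(f_hz, sample_rate, n) {
  if (any(f_hz < 0) || any(f_hz > sample_rate / 2)) {
    stop(sprintf("frequency %g Hz outside [0, Nyquist = %g Hz]",
                 f_hz[f_hz < 0 | f_hz > sample_rate / 2][1], sample_rate / 2),
         call. = FALSE)
  }
  # floor(x + 0.5) rounds exact .5 ties upward (unlike base round()).
  as.integer(floor(f_hz * n / sample_rate + 0.5))
}

#' Frequency of an FFT bin
#'
#' @param k 0-based bin index.
#' @param sample_rate Sampling rate in Hz.
#' @param n Number of samples in the transform.
#' @return Frequency in Hz.
#' @export
freq_of <- function(k, sample_rate, n) {
  k * sample_rate / n
}
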