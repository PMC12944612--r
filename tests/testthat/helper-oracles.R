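# Brute-force O(N^2) DFT oracle: PSD(k) = |sum_n y(n) e^{-i2pi kn/N}|^2 / N,
# independent of the package's FFT path.
naive_dft_psd <- function(y) {
  n <- length(y)
  ks <- seq_len(n) - 1
  vapply(ks, function(k) {
    x <- sum(y * exp(-2i * pi * k * (ks) / n))
    Mod(x)^2 / n
  }, numeric(1))
}

# A single-subject noiseless spec with one dominant alpha tone.
tone_subject <- function(iaf = 10, id = "tone", n_w = 2, n_s1 = 2, ...) {
  subject_spec(id, iaf_true = iaf, alpha_amp_wake = 1, alpha_atten_s1 = 0.3,
               slow_amp_wake = 0, slow_amp_s1 = 0.1, noise_amp = 0,
               n_wake_epochs = n_w, n_s1_epochs = n_s1, ...)
}

# Features of one synthetic subject, run through the full pipeline.
subject_features <- function(spec, sample_rate = 250, epoch_seconds = 30,
                             seed = 1, filter = TRUE, iaf_mode = "per_epoch") {
  coh <- generate_cohort(cohort_spec(list(spec), sample_rate = sample_rate,
                                     epoch_seconds = epoch_seconds, seed = seed))
  rec <- coh$recordings[[1]]
  if (filter) rec <- bandpass(rec)
  extract_features(segment(rec, coh$hypnograms[[1]]), iaf_mode = iaf_mode)
}

# Separable toy feature rows: drowsy at (1,...,1), alert at (-1,...,-1).
toy_separable_rows <- function(n_per_class = 20) {
  mk <- function(v, lab, off) {
    data.frame(subject_id = "toy", epoch_index = off + seq_len(n_per_class) - 1L,
               label = lab, p_iaf = v, p_tf = v, p_3hz = v, p_4hz = v,
               ratio_r = v, stringsAsFactors = FALSE)
  }
  rbind(mk(-1, "alert", 0L), mk(1, "drowsy", n_per_class))
}
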