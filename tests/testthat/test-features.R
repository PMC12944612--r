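flat_psd <- function(value = 1, n = 750, fs = 25) {
  # flat exposed spectrum covering 0..12.5 Hz at 1/30 Hz spacing
  psd_obj <- psd(rnorm(n), fs)
  psd_obj$power <- rep(value, length(psd_obj$power))
  psd_obj
}

test_that("IAF is the alpha-band argmax with low-frequency tie-breaking", {
  p <- flat_psd(0)
  k95 <- bin_of(9.5, p$sample_rate, p$n_samples)
  p$power[k95 + 1] <- 10
  expect_equal(find_iaf(p), freq_of(k95, p$sample_rate, p$n_samples))

  expect_equal(find_iaf(flat_psd(1)), 8.0)   # flat spectrum -> lowest bin

  # end-to-end: noiseless 11 Hz tone through the spectral path
  spec <- tone_subject(iaf = 11)
  set.seed(3)
  ep <- generate_epoch(spec, "W", 250, 30)
  expect_equal(find_iaf(psd(ep, 250)), 11.0)
})

test_that("IAF requires spectral coverage of the alpha band", {
  tiny <- psd(rnorm(8), sample_rate = 8)   # bins up to 4 Hz only
  expect_error(find_iaf(tiny), "8-12")
})

test_that("theta frequency is IAF minus 4 within bounds", {
  expect_equal(theta_frequency(10), 6)
  expect_equal(theta_frequency(8), 4)
  expect_equal(theta_frequency(12), 8)
  expect_error(theta_frequency(7.9), "8, 12")
})

test_that("band power ratio matches constructed band means", {
  expect_equal(band_power_ratio(flat_psd(1)), 1)

  p <- flat_psd(0)
  slow <- bin_of(3, p$sample_rate, p$n_samples):bin_of(4, p$sample_rate, p$n_samples)
  alpha <- bin_of(8, p$sample_rate, p$n_samples):bin_of(12, p$sample_rate, p$n_samples)
  p$power[slow + 1] <- 2
  p$power[alpha + 1] <- 1
  expect_equal(band_power_ratio(p), 2)

  p$power[alpha + 1] <- 0
  expect_error(band_power_ratio(p), "degenerate alpha band")
})

test_that("feature extraction conserves rows and separates states by construction", {
  spec <- subject_spec("n10", iaf_true = 10, alpha_amp_wake = 1,
                       alpha_atten_s1 = 0.3, slow_amp_wake = 0.3,
                       slow_amp_s1 = 0.9, noise_amp = 0,
                       n_wake_epochs = 5, n_s1_epochs = 5)
  res <- subject_features(spec, seed = 2)
  f <- res$features
  expect_identical(nrow(f), 10L)
  expect_setequal(f$label, c("alert", "drowsy"))
  expect_true(all(f$p_iaf[f$label == "alert"] > f$p_3hz[f$label == "alert"]))
  expect_gt(min(f$ratio_r[f$label == "drowsy"]), max(f$ratio_r[f$label == "alert"]))
})

test_that("powers are scale-equivariant and the ratio is scale-invariant", {
  spec <- tone_subject(n_w = 2, n_s1 = 1)
  coh <- generate_cohort(cohort_spec(list(spec), seed = 4))
  es <- segment(coh$recordings[[1]], coh$hypnograms[[1]])
  base <- extract_features(es)$features
  es_scaled <- es
  es_scaled$epochs <- lapply(es$epochs, function(e) 3 * e)
  scaled <- extract_features(es_scaled)$features
  for (col in c("p_iaf", "p_tf", "p_3hz", "p_4hz")) {
    expect_equal(scaled[[col]], 9 * base[[col]], tolerance = 1e-9)
  }
  expect_equal(scaled$ratio_r, base$ratio_r, tolerance = 1e-9)
})

test_that("subject_mean anchoring fixes one IAF with TF exactly 4 Hz below", {
  spec <- subject_spec("sm", iaf_true = 9.5, alpha_amp_wake = 1,
                       alpha_atten_s1 = 0.3, slow_amp_wake = 0.3,
                       slow_amp_s1 = 0.9, noise_amp = 0.5,
                       n_wake_epochs = 6, n_s1_epochs = 6)
  res <- subject_features(spec, seed = 5, iaf_mode = "subject_mean")
  expect_identical(length(unique(res$features$iaf_hz)), 1L)
  expect_equal(res$features$tf_hz, res$features$iaf_hz - 4)
  expect_identical(res$anchors$iaf_source, "subject_mean")
  expect_equal(res$anchors$tf_hz, res$anchors$iaf_hz - 4)
  expect_equal(res$anchors$iaf_hz, 9.5)
})

test_that("an all-zero epoch surfaces the degenerate-alpha error", {
  es <- structure(
    list(epochs = list(rep(0, 7500)), labels = "alert", epoch_index = 0L,
         sample_rate = 250, epoch_seconds = 30, subject_id = "z"),
    class = "epoch_set"
  )
  expect_error(extract_features(es), "degenerate alpha band")
})
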