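test_that("a pure-tone epoch peaks at its tone frequency and has the right length", {
  spec <- subject_spec("t", iaf_true = 10, alpha_amp_wake = 1,
                       slow_amp_wake = 0, slow_amp_s1 = 0.1, noise_amp = 0)
  set.seed(1)
  ep <- generate_epoch(spec, "W", sample_rate = 250, epoch_seconds = 30)
  expect_length(ep, 7500)
  p <- psd(ep, 250)
  expect_identical(which.max(p$power) - 1L, bin_of(10, 250, 7500))
})

test_that("an all-zero-amplitude S1 epoch is the null signal", {
  spec <- subject_spec("t", iaf_true = 10, alpha_amp_wake = 1,
                       alpha_atten_s1 = 0, slow_amp_wake = 0, slow_amp_s1 = 1e-12,
                       noise_amp = 0)
  set.seed(1)
  ep <- generate_epoch(spec, "S1", 250, 30)
  expect_lt(stats::var(ep), 1e-20)
})

test_that("invalid state labels are rejected by name", {
  spec <- tone_subject()
  expect_error(generate_epoch(spec, "REM"), "REM")
})

test_that("band powers move in the constructed direction between states", {
  spec <- subject_spec("t", iaf_true = 10, alpha_amp_wake = 1,
                       alpha_atten_s1 = 0.3, slow_amp_wake = 0.3,
                       slow_amp_s1 = 0.9, noise_amp = 0.5,
                       n_wake_epochs = 20, n_s1_epochs = 20)
  coh <- generate_cohort(cohort_spec(list(spec), seed = 7))
  es <- segment(coh$recordings[[1]], coh$hypnograms[[1]])
  band_mean <- function(ep, lo, hi) {
    p <- psd(ep, 250)
    bins <- bin_of(lo, 250, p$n_samples):bin_of(hi, 250, p$n_samples)
    mean(p$power[bins + 1])
  }
  alpha_w <- sapply(es$epochs[es$labels == "alert"], band_mean, 8, 12)
  alpha_s <- sapply(es$epochs[es$labels == "drowsy"], band_mean, 8, 12)
  slow_w <- sapply(es$epochs[es$labels == "alert"], band_mean, 3, 4)
  slow_s <- sapply(es$epochs[es$labels == "drowsy"], band_mean, 3, 4)
  expect_gt(mean(alpha_w), mean(alpha_s))
  expect_gt(mean(slow_s), mean(slow_w))
  # spectral separation: mean slow/alpha ratio higher in S1 than wake
  r <- sapply(es$epochs, function(e) band_power_ratio(psd(e, 250)))
  expect_gt(mean(r[es$labels == "drowsy"]), mean(r[es$labels == "alert"]))
})

test_that("cohort geometry and seeding contracts hold", {
  spec <- tone_subject(n_w = 2, n_s1 = 2)
  coh <- generate_cohort(cohort_spec(list(spec), sample_rate = 250,
                                     epoch_seconds = 30, seed = 11))
  expect_length(coh$recordings[[1]]$samples, 4 * 7500)
  expect_length(coh$hypnograms[[1]]$labels, 4)
  expect_setequal(coh$hypnograms[[1]]$labels, c("W", "S1"))

  coh2 <- generate_cohort(cohort_spec(list(spec), seed = 11))
  expect_identical(coh$recordings[[1]]$samples, coh2$recordings[[1]]$samples)
  expect_identical(coh$hypnograms[[1]]$labels, coh2$hypnograms[[1]]$labels)

  coh3 <- generate_cohort(cohort_spec(list(spec), seed = 12))
  expect_false(identical(coh$recordings[[1]]$samples, coh3$recordings[[1]]$samples))
})

test_that("subject and cohort spec invariants are enforced", {
  expect_error(subject_spec("a", iaf_true = 7), "8, 12")
  expect_error(subject_spec("a", 10, alpha_atten_s1 = 1), "alpha_atten_s1")
  expect_error(subject_spec("a", 10, slow_amp_wake = 1, slow_amp_s1 = 0.5),
               "slow_amp_s1")
  expect_error(subject_spec("a", 10, n_wake_epochs = 0, n_s1_epochs = 0),
               "at least one epoch")
  expect_error(cohort_spec(list(tone_subject()), sample_rate = 80), "Nyquist")
})

test_that("noise calibration scales with the square root of the target fraction", {
  a1 <- calibrate_noise_amp(target_fraction = 0.1, n_sim = 5)
  a2 <- calibrate_noise_amp(target_fraction = 0.4, n_sim = 5)
  expect_equal(a2 / a1, 2, tolerance = 1e-9)  # same internal seed, exact ratio
  expect_gt(a1, 0)
})
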