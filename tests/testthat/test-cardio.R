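make_test_ecg <- function(beat_times, dur, fs = 256, noise = 0.05,
                          seed = 1) {
  set.seed(seed)
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  v <- rnorm(n, 0, noise)
  for (b in beat_times) v <- v + exp(-((tt - b)^2) / (2 * 0.02^2))
  time_series(v, fs = fs, phase = "Forward", channel = "ecg")
}

test_that("preprocessing suppresses mains and DC but keeps the passband", {
  fs <- 256
  tt <- seq(0, 10, by = 1 / fs)

  mains <- time_series(sin(2 * pi * 50 * tt), fs = fs)
  filt <- suppressMessages(preprocess_ecg(mains))
  atten <- 20 * log10(sd(filt$values) / sd(mains$values))
  expect_lt(atten, -20)

  ecg <- make_test_ecg(seq(0.5, 9.5, by = 0.8), 10)
  shifted <- time_series(ecg$values + 5, fs = fs)
  out <- suppressMessages(preprocess_ecg(shifted))
  expect_lt(abs(mean(out$values)), 0.05)

  inband <- time_series(sin(2 * pi * 10 * tt), fs = fs)
  kept <- suppressMessages(preprocess_ecg(inband))
  expect_equal(sd(kept$values), sd(inband$values), tolerance = 0.05)

  expect_error(preprocess_ecg(time_series(rnorm(100), fs = 50)),
               "fs >= 100")
})

test_that("R peaks at known times give the expected RR intervals", {
  ecg <- make_test_ecg(c(1.0, 1.8, 2.6), 4)
  filt <- suppressMessages(preprocess_ecg(ecg))
  beats <- detect_r_peaks(filt)
  expect_length(beats, 3)
  rr <- rr_from_peaks(beats, 256)
  expect_equal(rr$rr, c(800, 800), tolerance = 1000 / 256 / 800)

  flat <- time_series(rep(0, 1000), fs = 256)
  expect_warning(b0 <- detect_r_peaks(flat), "threshold")
  expect_length(b0, 0)
})

test_that("peak detection is invariant to global amplitude scaling", {
  ecg <- make_test_ecg(seq(0.7, 19.5, by = 0.85), 20, seed = 5)
  filt <- suppressMessages(preprocess_ecg(ecg))
  b1 <- detect_r_peaks(filt)
  scaled <- time_series(filt$values * 37.5, fs = 256)
  expect_identical(detect_r_peaks(scaled), b1)
})

test_that("RR construction is exact and invertible", {
  rr <- rr_from_peaks(c(257, 513), 256)
  expect_equal(rr$rr, 1000)

  rr2 <- rr_from_peaks(c(1, 206, 411), 256)
  expect_equal(rr2$rr, c(205, 205) / 256 * 1000, tolerance = 1e-12)

  set.seed(41)
  beats <- cumsum(sample(150:300, 20))
  rr3 <- rr_from_peaks(beats, 256)
  expect_equal(diff(rr3$beat_times), rr3$rr / 1000, tolerance = 1e-12)
  expect_error(rr_from_peaks(c(100), 256), "at least 2")
})

test_that("time-domain HRV features match the defining formulas", {
  rr <- rr_from_peaks(cumsum(c(1, 800, 810, 790, 805)) * 0.256, 256)
  # construct directly to avoid quantization
  rr <- structure(list(beat_times = cumsum(c(0, 800, 810, 790, 805)) / 1000,
                       rr = c(800, 810, 790, 805)), class = "mw_rr")
  f <- hrv_time_features(rr)
  expect_equal(f[["RRmean"]], 801.25, tolerance = 1e-6)
  expect_equal(f[["SDNN"]], 8.5391, tolerance = 1e-3)
  expect_equal(f[["RMSSD"]], 15.5456, tolerance = 1e-3)

  const <- structure(list(beat_times = (0:9) * 0.8, rr = rep(800, 9)),
                     class = "mw_rr")
  fc <- hrv_time_features(const)
  expect_equal(unname(fc[c("SDNN", "RMSSD")]), c(0, 0))
})

test_that("SDNN of heavy Gaussian jitter concentrates at its true value", {
  set.seed(43)
  rrv <- 800 + rnorm(1e4, 0, 50)
  rr <- structure(list(beat_times = cumsum(c(0, rrv)) / 1000, rr = rrv),
                  class = "mw_rr")
  expect_equal(hrv_time_features(rr)[["SDNN"]], 50, tolerance = 2 / 50)
})

# beat train with sinusoidally modulated instantaneous RR, for the
# frequency-domain checks (independent of the package generator)
modulated_rr <- function(freq, amp, dur = 300, base = 850) {
  t <- 0; times <- numeric(0)
  while (t < dur) {
    times <- c(times, t)
    t <- t + (base + amp * sin(2 * pi * freq * t)) / 1000
  }
  structure(list(beat_times = times, rr = diff(times) * 1000),
            class = "mw_rr")
}

test_that("tachogram spectra localize LF and HF modulation", {
  lf_rr <- modulated_rr(0.10, 40)
  expect_gt(hrv_freq_features(lf_rr)[["LFHF"]], 10)

  hf_rr <- modulated_rr(0.25, 40)
  expect_lt(hrv_freq_features(hf_rr)[["LFHF"]], 0.1)

  const <- structure(list(beat_times = (0:399) * 0.85,
                          rr = rep(850, 399)), class = "mw_rr")
  fc <- hrv_freq_features(const)
  expect_equal(unname(fc[c("LF", "HF")]), c(0, 0))
  expect_true(is.na(fc[["LFHF"]]))
})

test_that("baseline normalization is an element-wise ratio with NA on zero", {
  f <- c(RRmean = 900, SDNN = 40, RMSSD = 30, LF = 2, HF = 1, LFHF = 2)
  b <- c(RRmean = 800, SDNN = 40, RMSSD = 30, LF = 2, HF = 1, LFHF = 2)
  r <- normalize_to_baseline(f, b)
  expect_equal(r[["RRmean"]], 1.125)
  expect_equal(unname(r[-1]), rep(1, 5))
  expect_true(attr(r, "normalized"))
  expect_error(normalize_to_baseline(r, b), "unnormalized")

  b2 <- b; b2[["SDNN"]] <- 0
  r2 <- suppressMessages(normalize_to_baseline(f, b2))
  expect_true(is.na(r2[["SDNN"]]))
  expect_equal(sum(!is.na(r2)), 5)
})

test_that("end-to-end RR recovery stays within 1% of the configured mean", {
  errs <- sapply(1:3, function(s) {
    cfg <- synth_config(n_subjects = 2, seed = s,
                        phase_durations = short_durations)
    coh <- generate_cohort(cfg)
    rec <- coh[[1]]
    ecg <- suppressMessages(preprocess_ecg(rec$ecg$BL))
    rr <- rr_from_peaks(detect_r_peaks(ecg), ecg$fs)
    true_mean <- 850 + rec$truth$rr_offset
    abs(hrv_time_features(rr)[["RRmean"]] - true_mean) / true_mean
  })
  expect_lt(max(errs), 0.01)
})
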