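test_that("ROI averaging reduces frames to per-frame masked means", {
  frames <- replicate(5, matrix(30, 4, 4), simplify = FALSE)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(roi_mean_series(frames, mask)$values, rep(30, 5))

  fr <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  mask2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # first row
  expect_equal(roi_mean_series(list(fr), mask2)$values, 1.5)

  set.seed(9)
  frames3 <- replicate(100, matrix(rnorm(36), 6, 6), simplify = FALSE)
  mask3 <- matrix(runif(36) > 0.5, 6, 6)
  oracle <- vapply(frames3, function(f) mean(f[mask3]), numeric(1))
  expect_identical(roi_mean_series(frames3, mask3)$values, oracle)

  expect_error(roi_mean_series(frames3, matrix(FALSE, 6, 6)), "no pixels")
  expect_error(roi_mean_series(frames3, matrix(TRUE, 3, 3)), "shape")
})

test_that("Hampel replaces an isolated spike and passes smooth signals", {
  z <- rep(0, 100); z[51] <- 10
  h <- hampel_filter(z, fs = 10)
  expect_equal(h$series[51], 0)
  expect_identical(which(h$outlier), 51L)

  ramp <- seq(0, 5, length.out = 200)
  h2 <- hampel_filter(ramp, fs = 10)
  expect_equal(h2$series, ramp)
  expect_false(any(h2$outlier))
})

test_that("Hampel matches the naive per-sample median/MAD oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(100:400, 1)
    x <- seq(0, 3, length.out = n) + rnorm(n, 0, 0.1)
    spikes <- sample(n, 5)
    x[spikes] <- x[spikes] + sample(c(-1, 1), 5, TRUE) * runif(5, 2, 5)
    got <- hampel_filter(x, fs = 10)
    want <- hampel_oracle(x, fs = 10)
    expect_identical(got$series, want$values)
    expect_identical(got$outlier, want$outlier)
  }
})

test_that("Hampel is idempotent and monotone in the threshold", {
  set.seed(33)
  x <- cumsum(rnorm(300, 0, 0.05))
  x[c(40, 140, 260)] <- x[c(40, 140, 260)] + 4
  once <- hampel_filter(x, fs = 10)
  twice <- hampel_filter(once$series, fs = 10)
  expect_identical(twice$series, once$series)

  counts <- vapply(c(1, 2, 4, 8), function(t)
    sum(hampel_filter(x, hampel_params(n_sd = t), fs = 10)$outlier),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline subtraction is exact arithmetic and channel-checked", {
  ph <- time_series(rep(31.2, 50), fs = 10, channel = "nosetip")
  bl <- time_series(rep(30.0, 600), fs = 10, channel = "nosetip")
  out <- baseline_subtract(ph, bl)
  expect_equal(out$values, rep(1.2, 50))
  back <- time_series(out$values + mean(bl$values), fs = 10,
                      channel = "nosetip")
  expect_equal(back$values, ph$values, tolerance = 1e-12)

  expect_error(baseline_subtract(
    ph, time_series(1:10, fs = 10, channel = "glabella")),
    "channel mismatch")
})

test_that("thermal feature vector composes the individual descriptors", {
  x <- time_series(sin(2 * pi * 0.10 * seq(0, 600, by = 0.1)), fs = 10,
                   phase = "Forward", channel = "nosetip")
  fv <- thermal_feature_vector(x)
  expect_named(fv, c("MeanTemp", "STD", "K", "S", "P90", "SampEn",
                     "LF", "HF", "LFHF"))
  expect_gt(fv[["LFHF"]], 10)
  expect_equal(fv[["MeanTemp"]], 0, tolerance = 1e-6)

  zero <- time_series(rep(0, 600), fs = 10)
  fz <- thermal_feature_vector(zero)
  expect_equal(unname(fz[c("MeanTemp", "STD", "SampEn", "LF", "HF")]),
               c(0, 0, 0, 0, 0))
  expect_true(is.na(fz[["LFHF"]]))

  set.seed(35)
  y <- rnorm(1200)
  ty <- time_series(y, fs = 10)
  fy <- thermal_feature_vector(ty)
  mom <- moment_features(y)
  expect_equal(fy[["MeanTemp"]], mom[["mean"]])
  expect_equal(fy[["STD"]], mom[["sd"]])
  expect_equal(fy[["S"]], mom[["skewness"]])
  expect_equal(fy[["K"]], mom[["kurtosis"]])
  expect_equal(fy[["P90"]], mom[["p90"]])
  expect_equal(fy[["SampEn"]], sample_entropy(y))
  expect_equal(unname(fy[c("LF", "HF", "LFHF")]),
               unname(band_features(estimate_spectrum(y, fs = 10))))
})

test_that("filtering positive spikes can only lower STD and P90", {
  set.seed(37)
  for (i in 1:5) {
    x <- 34 + cumsum(rnorm(600, 0, 0.02))
    spikes <- sample(600, 8)
    x[spikes] <- x[spikes] + 2
    raw <- time_series(x, fs = 10)
    cleaned <- hampel_filter(raw)$series
    expect_lte(sd(cleaned$values), sd(raw$values))
    expect_lte(quantile(cleaned$values, 0.9), quantile(raw$values, 0.9))
  }
})
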