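#' Frequency bands for spectral features
#'
#' The low-frequency (LF) and high-frequency (HF) bands used for both the
#' thermal ROI signals and the RR tachogram. Defaults are the standard HRV
#' bands: LF = 0.04--0.15 Hz, HF = 0.15--0.4 Hz.
#'
#' @param lf_low,lf_high,hf_low,hf_high band edges in Hz.
#' @return an object of class `mw_bands`.
#' @export
band_spec <- function(lf_low = 0.04, lf_high = 0.15,
                      hf_low = 0.15, hf_high = 0.4) {
  stopifnot(0 < lf_low, lf_low < lf_high, lf_high <= hf_low, hf_low < hf_high)
  structure(list(lf_low = lf_low, lf_high = lf_high,
                 hf_low = hf_low, hf_high = hf_high),
            class = "mw_bands")
}

#' Sample entropy parameters
#'
#' Embedding length `m` and tolerance factor `r_factor` (tolerance is
#' `r_factor * sd(x)`). Defaults m = 2, r = 0.2 sd are the field-standard
#' convention for physiological series.
#'
#' @param m embedding (template) length, >= 1.
#' @param r_factor tolerance as a multiple of the signal standard deviation.
#' @return an object of class `mw_sampen_params`.
#' @export
sampen_params <- function(m = 2L, r_factor = 0.2) {
  m <- as.integer(m)
  stopifnot(m >= 1L, r_factor > 0)
  structure(list(m = m, r_factor = r_factor), class = "mw_sampen_params")
}

#' Moment-based descriptors of a signal
#'
#' Mean, sample standard deviation (n-1 denominator), skewness, kurtosis and
#' the 90th percentile. Skewness and kurtosis are the biased moment ratios
#' m3/m2^1.5 and m4/m2^2; kurtosis is non-excess, so a Gaussian signal has
#' kurtosis 3. The percentile uses linear interpolation between order
#' statistics (inclusive endpoints). A zero-variance input yields `NA`
#' skewness and kurtosis rather than a silent zero.
#'
#' @param x numeric vector (or `mw_ts`) of length >= 4 with finite values.
#' @return named numeric vector `c(mean, sd, skewness, kurtosis, p90)`.
#' @export
#' @examples
#' moment_features(c(1, 2, 3, 4, 5))
moment_features <- function(x) {
  x <- as_ts_values(x)
  if (length(x) < 4L)
    stop("moment features require at least 4 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop("input contains non-finite values", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 <= 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  c(mean = mu,
    sd = stats::sd(x),
    skewness = skew,
    kurtosis = kurt,
    p90 = unname(stats::quantile(x, 0.9, type = 7)))
}

#' Sample entropy
#'
#' Regularity measure SampEn = -ln(A/B), where B counts pairs of m-length
#' templates within Chebyshev distance r of each other and A counts the same
#' for (m+1)-length templates; self-matches are excluded and the tolerance is
#' `r_factor * sd(x)`. A constant input returns 0 by convention; if no
#' m-template pair matches (B = 0) the value is undefined and `NA` is
#' returned; B > 0 with A = 0 gives `Inf` (no repeated (m+1)-patterns).
#'
#' @param x numeric vector or `mw_ts`, length >= m + 2.
#' @param params a [sampen_params()] object.
#' @return a single number (possibly `NA`).
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  x <- as_ts_values(x)
  m <- params$m
  if (length(x) < m + 2L)
    stop("sample entropy requires at least m + 2 samples", call. = FALSE)
  if (any(!is.finite(x)))
    stop("input contains non-finite values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- params$r_factor * s
  cnt <- .sampen_counts(x, m, r)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0) return(NA_real_)
  -log(A / B)
}

#' Welch power spectral density estimate
#'
#' Averaged-periodogram (Welch) estimate with a Hamming taper, 50% segment
#' overlap and per-segment linear detrending. The segment length defaults to
#' `min(N, 60 s * fs)` samples. The one-sided density is scaled so that its
#' integral over \[0, fs/2\] matches the detrended signal variance (Parseval
#' consistency, within ~10% for broadband signals).
#'
#' @param x numeric vector or `mw_ts`.
#' @param fs sampling rate in Hz (taken from `x` when it is an `mw_ts`).
#' @param segment_seconds segment length in seconds for periodogram
#'   averaging.
#' @param overlap fractional overlap between segments.
#' @return an object of class `mw_spectrum` with fields `frequencies`,
#'   `power`, `fs`, `segment_samples`, `overlap`, `detrend`.
#' @export
estimate_spectrum <- function(x, fs = NULL, segment_seconds = 60,
                              overlap = 0.5) {
  fs <- ts_fs(x, fs)
  x <- as_ts_values(x)
  n <- length(x)
  if (n < 8L)
    stop("spectral estimation requires at least 8 samples", call. = FALSE)
  seg <- min(n, max(8L, floor(segment_seconds * fs)))
  step <- max(1L, floor(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hamming
  u <- sum(w^2)
  nfreq <- seg %/% 2L + 1L
  acc <- numeric(nfreq)
  tt <- seq_len(seg)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1L)]
    seg_x <- stats::lm.fit(cbind(1, tt), seg_x)$residuals  # linear detrend
    ft <- stats::fft(seg_x * w)[seq_len(nfreq)]
    p <- Mod(ft)^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when seg is even)
    mult <- rep(2, nfreq)
    mult[1] <- 1
    if (seg %% 2L == 0L) mult[nfreq] <- 1
    acc <- acc + p * mult
  }
  structure(
    list(frequencies = (seq_len(nfreq) - 1) * fs / seg,
         power = acc / length(starts),
         fs = fs, segment_samples = seg, overlap = overlap, detrend = TRUE),
    class = "mw_spectrum"
  )
}

#' @export
print.mw_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mw_spectrum> %d bins, 0-%.3g Hz (fs=%g, segment=%d samples, overlap=%g)\n",
    length(x$frequencies), max(x$frequencies), x$fs, x$segment_samples,
    x$overlap))
  invisible(x)
}

# Trapezoidal integral of the PSD over [lo, hi], with power linearly
# interpolated at the band edges so the integration range is exact.
band_integral <- function(freqs, power, lo, hi) {
  if (lo < min(freqs) - 1e-12 || hi > max(freqs) + 1e-12)
    stop(sprintf("band [%g, %g] Hz outside spectral range [%g, %g] Hz",
                 lo, hi, min(freqs), max(freqs)), call. = FALSE)
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  p <- c(stats::approx(freqs, power, xout = lo)$y,
         power[inside],
         stats::approx(freqs, power, xout = hi)$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Band-limited spectral power features
#'
#' Mean power density in the LF and HF bands (trapezoidal integral of the
#' PSD over the band divided by the band width) and their ratio LF/HF.
#' When the HF power is zero the ratio is undefined and returned as `NA`.
#'
#' @param spec an `mw_spectrum` from [estimate_spectrum()].
#' @param bands a [band_spec()] object.
#' @return named numeric vector `c(LF, HF, LFHF)`.
#' @export
band_features <- function(spec, bands = band_spec()) {
  stopifnot(inherits(spec, "mw_spectrum"))
  lf <- band_integral(spec$frequencies, spec$power,
                      bands$lf_low, bands$lf_high) /
    (bands$lf_high - bands$lf_low)
  hf <- band_integral(spec$frequencies, spec$power,
                      bands$hf_low, bands$hf_high) /
    (bands$hf_high - bands$hf_low)
  ratio <- if (hf == 0) NA_real_ else lf / hf
  c(LF = lf, HF = hf, LFHF = ratio)
}
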