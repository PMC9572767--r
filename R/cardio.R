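#' ECG preprocessing parameters
#'
#' Band-pass edges, mains-notch frequency, R-peak refractory period and the
#' detection threshold (in standard deviations above the mean). The nominal
#' 150 Hz upper cutoff exceeds the Nyquist frequency at the usual 256 Hz
#' sampling, so the effective high cutoff is capped at `0.45 * fs` (a notice
#' is emitted when the cap engages).
#'
#' @param bp_low,bp_high band-pass edges in Hz.
#' @param notch mains frequency to suppress, Hz.
#' @param refractory minimum spacing between detected beats, seconds.
#' @param z_threshold detection threshold in whole-phase standard deviations.
#' @return an object of class `mw_ecg_params`.
#' @export
ecg_preproc_params <- function(bp_low = 0.05, bp_high = 150, notch = 50,
                               refractory = 0.25, z_threshold = 2) {
  stopifnot(bp_low > 0, bp_low < bp_high, notch > bp_low, notch < bp_high,
            refractory > 0, z_threshold > 0)
  structure(list(bp_low = bp_low, bp_high = bp_high, notch = notch,
                 refractory = refractory, z_threshold = z_threshold),
            class = "mw_ecg_params")
}

#' Band-pass and notch filtering of raw ECG
#'
#' Zero-phase (forward-backward) filtering: a first-order Butterworth
#' high-pass at `bp_low`, a fourth-order Butterworth low-pass at
#' `min(bp_high, 0.45 fs)`, and a second-order Butterworth band-stop of
#' +/- 2 Hz around the mains frequency. Output length equals input length.
#'
#' @param x raw ECG (`mw_ts`), `fs >= 100` Hz.
#' @param params an [ecg_preproc_params()] object.
#' @return filtered `mw_ts`.
#' @export
preprocess_ecg <- function(x, params = ecg_preproc_params()) {
  stopifnot(inherits(x, "mw_ts"))
  fs <- x$fs
  if (fs < 100)
    stop("ECG preprocessing requires fs >= 100 Hz", call. = FALSE)
  hi <- min(params$bp_high, 0.45 * fs)
  if (hi < params$bp_high)
    message(sprintf("high cutoff capped at %.1f Hz (0.45 * fs)", hi))
  nyq <- fs / 2
  v <- x$values - mean(x$values)  # remove DC before the slow high-pass
  hp <- signal::butter(1, params$bp_low / nyq, type = "high")
  v <- signal::filtfilt(hp, v)
  lp <- signal::butter(4, hi / nyq, type = "low")
  v <- signal::filtfilt(lp, v)
  if (params$notch < hi) {
    bs <- signal::butter(2, c(params$notch - 2, params$notch + 2) / nyq,
                         type = "stop")
    v <- signal::filtfilt(bs, v)
  }
  time_series(v, fs = fs, phase = x$phase, channel = x$channel)
}

#' Threshold-based R-peak detection
#'
#' Local maxima whose amplitude exceeds the whole-phase mean plus
#' `z_threshold` standard deviations are taken as R peaks; candidates closer
#' together than the refractory period are resolved in favour of the larger
#' peak (amplitude-priority, deterministic). Positive R-wave polarity is
#' assumed. The threshold is relative, so the detector is invariant to
#' global amplitude scaling. Before peak picking the signal is smoothed
#' with a short Gaussian kernel (`smooth_seconds` SD, default 10 ms) --
#' an approximate matched filter for the R wave that stabilises the
#' argmax location against broadband noise without displacing the
#' (symmetric) peak.
#'
#' @param x preprocessed ECG (`mw_ts`).
#' @param params an [ecg_preproc_params()] object.
#' @param smooth_seconds SD of the Gaussian localisation kernel, seconds;
#'   0 disables smoothing.
#' @return integer vector of beat sample indices (1-based), possibly empty
#'   (with a warning) when nothing crosses the threshold.
#' @export
detect_r_peaks <- function(x, params = ecg_preproc_params(),
                           smooth_seconds = 0.010) {
  stopifnot(inherits(x, "mw_ts"))
  v <- x$values
  if (smooth_seconds > 0) {
    ks <- smooth_seconds * x$fs
    half <- max(1L, ceiling(3 * ks))
    kern <- stats::dnorm(seq(-half, half), sd = ks)
    kern <- kern / sum(kern)
    v <- as.numeric(stats::filter(v, kern, sides = 2))
    # filter() leaves NAs at the edges; pad with the nearest valid value
    ok <- which(!is.na(v))
    v[seq_len(ok[1] - 1L)] <- v[ok[1]]
    v[seq.int(ok[length(ok)] + 1L, length.out = length(v) - ok[length(ok)])] <-
      v[ok[length(ok)]]
  }
  n <- length(v)
  thr <- mean(v) + params$z_threshold * stats::sd(v)
  if (n < 3L || !any(v > thr)) {
    warning("no samples exceed the R-peak threshold; empty beat list",
            call. = FALSE)
    return(integer(0))
  }
  mid <- 2:(n - 1L)
  is_max <- v[mid] > v[mid - 1L] & v[mid] >= v[mid + 1L] & v[mid] > thr
  cand <- mid[is_max]
  if (length(cand) == 0L) {
    warning("no local maxima exceed the R-peak threshold", call. = FALSE)
    return(integer(0))
  }
  gap <- params$refractory * x$fs
  ord <- cand[order(-v[cand], cand)]  # largest first, index tie-break
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L || all(abs(keep - i) >= gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' RR interval series from beat indices
#'
#' @param beat_indices integer beat sample positions (1-based), >= 2 beats.
#' @param fs sampling rate of the source ECG in Hz.
#' @return an object of class `mw_rr` with `beat_times` (s, strictly
#'   increasing) and `rr` (ms, one fewer than the beats).
#' @export
rr_from_peaks <- function(beat_indices, fs) {
  beat_indices <- sort(as.numeric(beat_indices))
  if (length(beat_indices) < 2L)
    stop("at least 2 beats are required to form RR intervals", call. = FALSE)
  bt <- (beat_indices - 1) / fs
  rr <- diff(bt) * 1000
  if (any(rr <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  structure(list(beat_times = bt, rr = rr), class = "mw_rr")
}

#' @export
print.mw_rr <- function(x, ...) {
  cat(sprintf("<mw_rr> %d beats over %.1f s, mean RR %.1f ms\n",
              length(x$beat_times), diff(range(x$beat_times)), mean(x$rr)))
  invisible(x)
}

#' Time-domain HRV features
#'
#' RRmean (mean RR interval), SDNN (sample standard deviation of the RR
#' intervals) and RMSSD (root mean square of successive RR differences), all
#' in milliseconds. SDNN is `NA` when fewer than 4 intervals are available.
#'
#' @param rr an `mw_rr` object with at least 2 intervals.
#' @return named numeric vector `c(RRmean, SDNN, RMSSD)`.
#' @export
#' @examples
#' rr <- structure(list(beat_times = cumsum(c(0, 800, 810, 790, 805)) / 1000,
#'                      rr = c(800, 810, 790, 805)), class = "mw_rr")
#' hrv_time_features(rr)
hrv_time_features <- function(rr) {
  stopifnot(inherits(rr, "mw_rr"))
  if (length(rr$rr) < 2L)
    stop("time-domain HRV requires at least 2 RR intervals", call. = FALSE)
  c(RRmean = mean(rr$rr),
    SDNN = if (length(rr$rr) >= 4L) stats::sd(rr$rr) else NA_real_,
    RMSSD = sqrt(mean(diff(rr$rr)^2)))
}

#' Frequency-domain HRV features
#'
#' The RR tachogram (an unevenly sampled series of interval durations at the
#' beat times) is resampled to an even 4 Hz grid by cubic-spline
#' interpolation, its Welch spectrum estimated, and mean LF/HF band power
#' densities and their ratio extracted. Records shorter than `2 / lf_low`
#' seconds trigger a warning (band resolution becomes unreliable).
#'
#' @param rr an `mw_rr` object with at least 4 beats.
#' @param bands a [band_spec()] object.
#' @param resample_hz tachogram resampling rate, Hz.
#' @return named numeric vector `c(LF, HF, LFHF)`.
#' @export
hrv_freq_features <- function(rr, bands = band_spec(), resample_hz = 4) {
  stopifnot(inherits(rr, "mw_rr"))
  if (length(rr$beat_times) < 4L)
    stop("frequency-domain HRV requires at least 4 beats", call. = FALSE)
  span <- diff(range(rr$beat_times))
  if (span < 2 / bands$lf_low)
    warning("record shorter than recommended for LF estimation",
            call. = FALSE)
  # tachogram: rr[i] attributed to the time of the closing beat
  tt <- rr$beat_times[-1]
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  even <- stats::spline(tt, rr$rr, xout = grid, method = "fmm")$y
  if (stats::sd(even) == 0)
    return(c(LF = 0, HF = 0, LFHF = NA_real_))  # constant tachogram
  band_features(estimate_spectrum(even, fs = resample_hz), bands)
}

#' Normalize HRV features to the baseline phase
#'
#' Element-wise ratio between a phase's HRV features and the same features
#' computed on the baseline (undisturbed driving) phase. A zero baseline
#' entry makes the corresponding ratio undefined (`NA`).
#'
#' @param phase_features,baseline_features named numeric vectors with the
#'   same feature names (e.g. from [hrv_time_features()] and
#'   [hrv_freq_features()] combined).
#' @return named numeric vector of ratios with attribute
#'   `normalized = TRUE`.
#' @export
normalize_to_baseline <- function(phase_features, baseline_features) {
  if (!identical(names(phase_features), names(baseline_features)))
    stop("feature sets differ between phase and baseline", call. = FALSE)
  if (isTRUE(attr(phase_features, "normalized")) ||
      isTRUE(attr(baseline_features, "normalized")))
    stop("inputs must be unnormalized feature vectors", call. = FALSE)
  out <- phase_features / baseline_features
  zero <- !is.na(baseline_features) & baseline_features == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    message("baseline zero for: ", paste(names(out)[zero], collapse = ", "),
            " -- ratio set to NA")
  }
  attr(out, "normalized") <- TRUE
  out
}
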