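#' Hampel filter parameters
#'
#' `window_seconds` is the TOTAL centered window span (15 s at 10 Hz is 150
#' samples, about 75 each side), truncated at the series edges. `n_sd` is the
#' rejection threshold as a multiple of the robust dispersion 1.4826 * MAD.
#'
#' @param window_seconds total window span in seconds.
#' @param n_sd threshold multiplier.
#' @return an object of class `mw_hampel_params`.
#' @export
hampel_params <- function(window_seconds = 15, n_sd = 2) {
  stopifnot(window_seconds > 0, n_sd > 0)
  structure(list(window_seconds = window_seconds, n_sd = n_sd),
            class = "mw_hampel_params")
}

#' Average a thermal ROI over time
#'
#' Reduces a sequence of 2-D intensity frames to one trace: for each frame,
#' the mean of the pixels selected by a boolean ROI mask.
#'
#' @param frames a list of numeric matrices (one per frame) or a 3-D array
#'   with time on the third dimension.
#' @param mask logical matrix with the same 2-D shape as each frame,
#'   selecting at least one pixel.
#' @param fs frame rate in Hz.
#' @param phase,channel annotations for the resulting series.
#' @return an `mw_ts` with one sample per frame.
#' @export
roi_mean_series <- function(frames, mask, fs = 10, phase = NA_character_,
                            channel = NA_character_) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("ROI mask selects no pixels", call. = FALSE)
  vals <- vapply(frames, function(fr) {
    if (!identical(dim(fr), dim(mask)))
      stop("frame shape does not match mask shape", call. = FALSE)
    mean(fr[mask])
  }, numeric(1))
  time_series(vals, fs = fs, phase = phase, channel = channel)
}

#' Hampel outlier rejection
#'
#' Sliding-window robust outlier detector: each sample is compared with the
#' median of a centered window (truncated at the edges); samples deviating
#' from it by more than `n_sd` times the scaled median absolute deviation
#' (1.4826 * MAD) are replaced by the local median. Decisions are made
#' against the original samples, so the filter is idempotent in practice.
#'
#' @param x an `mw_ts` or numeric vector (then `fs` is required).
#' @param params a [hampel_params()] object.
#' @param fs sampling rate, only for bare numeric input.
#' @return list with `series` (filtered, same class as input) and `outlier`
#'   (logical mask of replaced samples).
#' @export
hampel_filter <- function(x, params = hampel_params(), fs = NULL) {
  fs <- ts_fs(x, fs)
  vals <- as_ts_values(x)
  if (length(vals) < 3L)
    stop("Hampel filter requires at least 3 samples", call. = FALSE)
  w <- floor(params$window_seconds * fs)
  if (w < 3L)
    stop("Hampel window spans fewer than 3 samples at this rate",
         call. = FALSE)
  half <- w %/% 2L
  res <- .hampel_core(vals, half, params$n_sd)
  out <- if (inherits(x, "mw_ts")) {
    time_series(res$values, fs = fs, phase = x$phase, channel = x$channel)
  } else res$values
  list(series = out, outlier = res$outlier)
}

#' Subtract the pre-task baseline level
#'
#' Subtracts the mean of a baseline window (by convention the final 60 s of
#' undisturbed driving before the first cognitive task) from a phase signal,
#' expressing thermal traces as deviations from the subject's resting level.
#' The same baseline window is used for every phase.
#'
#' @param x phase signal (`mw_ts`).
#' @param baseline baseline window (`mw_ts`), same channel as `x`.
#' @return an `mw_ts` with the baseline mean removed.
#' @export
baseline_subtract <- function(x, baseline) {
  stopifnot(inherits(x, "mw_ts"), inherits(baseline, "mw_ts"))
  if (!is.na(x$channel) && !is.na(baseline$channel) &&
      x$channel != baseline$channel)
    stop(sprintf("channel mismatch: signal is '%s' but baseline is '%s'",
                 x$channel, baseline$channel), call. = FALSE)
  time_series(x$values - mean(baseline$values), fs = x$fs,
              phase = x$phase, channel = x$channel)
}

# Last `seconds` of a series, used to carve the baseline window out of the
# BL phase trace.
tail_window <- function(x, seconds = 60) {
  stopifnot(inherits(x, "mw_ts"))
  n <- length(x$values)
  keep <- min(n, max(1L, round(seconds * x$fs)))
  time_series(x$values[(n - keep + 1L):n], fs = x$fs,
              phase = x$phase, channel = x$channel)
}

#' Nine-feature thermal descriptor vector
#'
#' The per-phase thermal feature set: mean (MeanTemp), standard deviation
#' (STD), kurtosis (K), skewness (S), 90th percentile (P90), sample entropy
#' (SampEn), mean LF and HF band power densities, and their ratio (LFHF).
#' The input is expected to be Hampel-cleaned and baseline-subtracted.
#' Undefined entries (zero-variance skewness/kurtosis, zero-HF ratio)
#' propagate as `NA`.
#'
#' @param x an `mw_ts` (thermal ROI trace for one phase).
#' @param sampen a [sampen_params()] object.
#' @param bands a [band_spec()] object.
#' @return named numeric vector of length 9, ordered
#'   `MeanTemp, STD, K, S, P90, SampEn, LF, HF, LFHF`.
#' @export
thermal_feature_vector <- function(x, sampen = sampen_params(),
                                   bands = band_spec()) {
  stopifnot(inherits(x, "mw_ts"))
  vals <- x$values
  if (length(vals) < 4L)
    stop("thermal features require at least 4 samples", call. = FALSE)
  mom <- moment_features(vals)
  se <- if (stats::sd(vals) == 0) 0 else sample_entropy(vals, sampen)
  if (length(vals) < 2 * x$fs / bands$lf_low)
    warning("signal shorter than recommended for spectral estimation",
            call. = FALSE)
  bf <- if (stats::sd(vals) == 0) {
    c(LF = 0, HF = 0, LFHF = NA_real_)  # flat signal carries no power
  } else {
    band_features(estimate_spectrum(vals, fs = x$fs), bands)
  }
  c(MeanTemp = unname(mom["mean"]), STD = unname(mom["sd"]),
    K = unname(mom["kurtosis"]), S = unname(mom["skewness"]),
    P90 = unname(mom["p90"]), SampEn = se,
    LF = unname(bf["LF"]), HF = unname(bf["HF"]), LFHF = unname(bf["LFHF"]))
}
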