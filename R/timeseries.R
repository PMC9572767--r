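#' Uniformly sampled physiological time series
#'
#' Lightweight container used throughout the pipeline for thermal
#' region-of-interest (ROI) traces and raw ECG. Carries the sampling rate,
#' the experimental phase the samples belong to, and a channel tag
#' (`"nosetip"`, `"glabella"` or `"ecg"`).
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (thermal imaging is typically 10 Hz, ECG
#'   256 Hz).
#' @param phase experimental phase label (e.g. `"BL"`, `"Forward"`,
#'   `"DelR"`), or `NA`.
#' @param channel channel identifier, or `NA`.
#' @return an object of class `mw_ts`.
#' @export
#' @examples
#' ts <- time_series(sin(seq(0, 10, by = 0.1)), fs = 10, phase = "BL",
#'                   channel = "nosetip")
#' ts
time_series <- function(values, fs, phase = NA_character_,
                        channel = NA_character_) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(values) < 1L)
    stop("`values` must contain at least one sample", call. = FALSE)
  structure(
    list(values = values, fs = fs,
         phase = as.character(phase), channel = as.character(channel)),
    class = "mw_ts"
  )
}

#' @export
print.mw_ts <- function(x, ...) {
  cat(sprintf("<mw_ts> %d samples @ %g Hz (%.1f s), phase=%s, channel=%s\n",
              length(x$values), x$fs, length(x$values) / x$fs,
              x$phase, x$channel))
  invisible(x)
}

#' @export
length.mw_ts <- function(x) length(x$values)

# Accept either an mw_ts or a bare numeric vector (fs then required).
as_ts_values <- function(x) {
  if (inherits(x, "mw_ts")) x$values else as.numeric(x)
}

ts_fs <- function(x, fs = NULL) {
  if (inherits(x, "mw_ts")) x$fs
  else if (!is.null(fs)) fs
  else stop("sampling rate `fs` required for bare numeric input",
            call. = FALSE)
}
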