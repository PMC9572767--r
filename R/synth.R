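#' Configuration of the synthetic driving-protocol cohort
#'
#' Describes a cohort of simulated drivers monitored through facial
#' thermography (10 Hz) and single-lead ECG (256 Hz) across a baseline
#' driving phase (`BL`) and five cognitive sub-phases: Digit Span forward
#' and backward (`Forward`, `Backward`) and verbal-learning immediate
#' recall, delayed recall and recognition (`ImmR`, `DelR`, `Rec`).
#'
#' Thermal traces are built as subject offset + per-phase mean shift +
#' LF/HF sinusoidal components (0.10 and 0.25 Hz, the band centers) + AR(1)
#' noise + Poisson-placed positive spike artifacts. ECG is built as
#' unit-amplitude Gaussian R waves (20 ms width) placed on a beat train
#' whose instantaneous RR interval is `rr_mean(phase) + lf * sin(2 pi 0.10
#' t) + hf * sin(2 pi 0.25 t) + noise`. The defaults emulate the canonical
#' workload physiology: a nose-tip temperature drop and RR shortening with
#' a raised LF/HF under higher cognitive load.
#'
#' @param n_subjects number of simulated drivers (>= 2).
#' @param seed master seed; each subject derives an independent substream,
#'   so enlarging the cohort never perturbs existing subjects.
#' @param phase_durations named vector of phase durations in seconds.
#' @param thermal_rate,ecg_rate sampling rates, Hz.
#' @param nose_effect,glabella_effect per-phase mean shifts
#'   (degC-equivalent) relative to the resting skin level.
#' @param lf_amp,hf_amp per-phase thermal oscillation amplitudes (degC).
#' @param rr_mean per-phase mean RR interval, ms.
#' @param rr_lf_amp,rr_hf_amp per-phase RR modulation amplitudes, ms.
#' @param subject_sd between-subject thermal offset SD (degC).
#' @param rr_subject_sd between-subject RR offset SD (ms).
#' @param noise_sd marginal SD of the AR(1) thermal noise (degC).
#' @param rr_noise_sd per-beat RR jitter SD (ms).
#' @param ecg_noise_sd additive ECG noise SD (R wave has unit amplitude).
#' @param artifact_rate thermal spike artifacts per minute.
#' @param artifact_amplitude spike magnitude (degC, positive).
#' @param base_temp resting ROI levels, degC-equivalent counts.
#' @param null_mode if `TRUE`, all per-phase generative parameters are
#'   forced to their baseline values, removing every phase effect (for
#'   chance-level and type-I-error checks).
#' @return an object of class `mw_synth_config`.
#' @export
synth_config <- function(
    n_subjects = 26L,
    seed = 1L,
    phase_durations = c(BL = 900, Forward = 120, Backward = 120,
                        ImmR = 120, DelR = 120, Rec = 120),
    thermal_rate = 10,
    ecg_rate = 256,
    nose_effect = c(BL = 0, Forward = -0.3, Backward = -0.6,
                    ImmR = -0.3, DelR = -0.7, Rec = -0.2),
    glabella_effect = c(BL = 0, Forward = 0.10, Backward = 0.20,
                        ImmR = 0.10, DelR = 0.25, Rec = 0.05),
    lf_amp = c(BL = 0.05, Forward = 0.08, Backward = 0.12,
               ImmR = 0.08, DelR = 0.14, Rec = 0.06),
    hf_amp = c(BL = 0.05, Forward = 0.05, Backward = 0.05,
               ImmR = 0.05, DelR = 0.05, Rec = 0.05),
    rr_mean = c(BL = 850, Forward = 820, Backward = 790,
                ImmR = 820, DelR = 780, Rec = 830),
    rr_lf_amp = c(BL = 20, Forward = 30, Backward = 40,
                  ImmR = 30, DelR = 45, Rec = 25),
    rr_hf_amp = c(BL = 25, Forward = 25, Backward = 25,
                  ImmR = 25, DelR = 25, Rec = 25),
    subject_sd = 0.3,
    rr_subject_sd = 50,
    noise_sd = 0.1,
    rr_noise_sd = 10,
    ecg_noise_sd = 0.05,
    artifact_rate = 2,
    artifact_amplitude = 2,
    base_temp = c(nosetip = 34, glabella = 35),
    null_mode = FALSE) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  stopifnot(thermal_rate > 0, ecg_rate > 0, all(phase_durations > 0),
            artifact_rate >= 0, noise_sd >= 0, subject_sd >= 0)
  phases <- names(phase_durations)
  if (is.null(phases) || anyDuplicated(phases) || !"BL" %in% phases)
    stop("phase_durations must be uniquely named and include 'BL'",
         call. = FALSE)
  expand <- function(v) {
    if (length(v) == 1L) v <- stats::setNames(rep(v, length(phases)), phases)
    if (!all(phases %in% names(v)))
      stop("per-phase parameter missing entries for some phases",
           call. = FALSE)
    v[phases]
  }
  cfg <- list(
    n_subjects = n_subjects, seed = as.integer(seed),
    phase_durations = phase_durations, phases = phases,
    thermal_rate = thermal_rate, ecg_rate = ecg_rate,
    nose_effect = expand(nose_effect),
    glabella_effect = expand(glabella_effect),
    lf_amp = expand(lf_amp), hf_amp = expand(hf_amp),
    rr_mean = expand(rr_mean),
    rr_lf_amp = expand(rr_lf_amp), rr_hf_amp = expand(rr_hf_amp),
    subject_sd = subject_sd, rr_subject_sd = rr_subject_sd,
    noise_sd = noise_sd, rr_noise_sd = rr_noise_sd,
    ecg_noise_sd = ecg_noise_sd,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    base_temp = base_temp, null_mode = isTRUE(null_mode))
  if (cfg$null_mode) {
    for (f in c("nose_effect", "glabella_effect", "lf_amp", "hf_amp",
                "rr_mean", "rr_lf_amp", "rr_hf_amp"))
      cfg[[f]][] <- cfg[[f]][["BL"]]
  }
  structure(cfg, class = "mw_synth_config")
}

# AR(1) noise with coefficient 0.9, scaled so the marginal SD is `sd`.
ar1_noise <- function(n, sd, phi = 0.9) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Beat train over [0, duration): t_{k+1} = t_k + rr(t_k)/1000 with the
# LF/HF-modulated instantaneous RR. Returns beat times in seconds.
rr_train <- function(duration, rr_mean, lf, hf, noise_sd, min_rr = 250,
                     phase = "?") {
  if (duration * 1000 < 2 * rr_mean)
    stop(sprintf("phase '%s' is too short to hold two beats", phase),
         call. = FALSE)
  times <- numeric(ceiling(duration * 1000 / max(min_rr, 1)) + 2L)
  t <- stats::runif(1, 0, rr_mean / 1000)  # random first-beat offset
  k <- 0L
  while (t < duration) {
    k <- k + 1L
    times[k] <- t
    rr <- rr_mean + lf * sin(2 * pi * 0.10 * t) +
      hf * sin(2 * pi * 0.25 * t) + stats::rnorm(1, 0, noise_sd)
    rr <- max(rr, min_rr)
    t <- t + rr / 1000
  }
  times[seq_len(k)]
}

# Gaussian R bumps (sd `width` seconds, unit amplitude) at `beats` on a grid
# of n samples at rate fs, plus white noise.
ecg_from_beats <- function(beats, n, fs, noise_sd, width = 0.02) {
  sig <- stats::rnorm(n, 0, noise_sd)
  tt <- (seq_len(n) - 1) / fs
  halfspan <- ceiling(4 * width * fs)
  for (b in beats) {
    c0 <- round(b * fs) + 1
    idx <- max(1, c0 - halfspan):min(n, c0 + halfspan)
    sig[idx] <- sig[idx] + exp(-((tt[idx] - b)^2) / (2 * width^2))
  }
  sig
}

generate_subject <- function(config, i) {
  sid <- sprintf("S%02d", i)
  set.seed((config$seed %% 100000L) * 20011L + i * 101L)
  thermal_off <- stats::rnorm(1, 0, config$subject_sd)
  rr_off <- stats::rnorm(1, 0, config$rr_subject_sd)

  thermal <- list(nosetip = list(), glabella = list())
  artifacts <- list(nosetip = list(), glabella = list())
  ecg <- list()
  beat_truth <- list()

  for (ph in config$phases) {
    dur <- config$phase_durations[[ph]]
    n <- round(dur * config$thermal_rate)
    tt <- (seq_len(n) - 1) / config$thermal_rate
    for (roi in c("nosetip", "glabella")) {
      eff <- if (roi == "nosetip") config$nose_effect[[ph]]
             else config$glabella_effect[[ph]]
      ph_lf <- stats::runif(1, 0, 2 * pi)
      ph_hf <- stats::runif(1, 0, 2 * pi)
      v <- config$base_temp[[roi]] + thermal_off + eff +
        config$lf_amp[[ph]] * sin(2 * pi * 0.10 * tt + ph_lf) +
        config$hf_amp[[ph]] * sin(2 * pi * 0.25 * tt + ph_hf) +
        ar1_noise(n, config$noise_sd)
      n_spk <- stats::rpois(1, config$artifact_rate * dur / 60)
      spk <- sort(sample.int(n, min(n_spk, n)))
      v[spk] <- v[spk] + config$artifact_amplitude
      thermal[[roi]][[ph]] <- time_series(v, fs = config$thermal_rate,
                                          phase = ph, channel = roi)
      artifacts[[roi]][[ph]] <- spk
    }
    beats <- rr_train(dur, config$rr_mean[[ph]] + rr_off,
                      config$rr_lf_amp[[ph]], config$rr_hf_amp[[ph]],
                      config$rr_noise_sd, phase = ph)
    n_ecg <- round(dur * config$ecg_rate)
    ecg[[ph]] <- time_series(
      ecg_from_beats(beats, n_ecg, config$ecg_rate, config$ecg_noise_sd),
      fs = config$ecg_rate, phase = ph, channel = "ecg")
    beat_truth[[ph]] <- beats
  }

  structure(
    list(subject_id = sid,
         thermal = thermal,
         ecg = ecg,
         baseline_thermal = list(
           nosetip = tail_window(thermal$nosetip$BL, 60),
           glabella = tail_window(thermal$glabella$BL, 60)),
         truth = list(beat_times = beat_truth, artifacts = artifacts,
                      thermal_offset = thermal_off, rr_offset = rr_off)),
    class = "mw_subject")
}

#' Generate a synthetic cohort
#'
#' Produces one record per simulated subject: thermal traces for the nose
#' tip and glabella ROIs and an ECG trace for every phase, a 60-s thermal
#' baseline window (the end of the `BL` phase), and ground truth (true beat
#' times and injected artifact indices) for oracle tests. Fully
#' deterministic for a fixed seed.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `mw_cohort`: a list of subject records with
#'   the configuration attached as attribute `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 2,
#'   phase_durations = c(BL = 120, Forward = 60, Backward = 60,
#'                       ImmR = 60, DelR = 60, Rec = 60)))
#' cohort[[1]]$thermal$nosetip$Forward
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mw_synth_config"))
  records <- lapply(seq_len(config$n_subjects),
                    function(i) generate_subject(config, i))
  names(records) <- vapply(records, `[[`, "", "subject_id")
  structure(records, class = "mw_cohort", config = config)
}

#' @export
print.mw_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<mw_cohort> %d subjects, phases: %s\n",
              length(x), paste(cfg$phases, collapse = ", ")))
  invisible(x)
}

#' Generate correlated cognitive-test scores
#'
#' Per-subject scores for the five cognitive sub-tests, drawn as jointly
#' Gaussian with a common within-subject correlation. Default means and
#' standard deviations are typical published cohort statistics for these
#' tests (digit span around 6-7 digits; verbal-learning immediate recall in
#' the low 40s over five repetitions).
#'
#' @param config a [synth_config()] object (supplies `n_subjects`, `seed`).
#' @param means,sds named numeric vectors of score means and SDs.
#' @param correlation common pairwise correlation between a subject's
#'   scores, in \[0, 1).
#' @return a data.frame with `subject_id` and one column per score.
#' @export
generate_scores <- function(
    config,
    means = c(Forward = 7.19, Backward = 6.15,
              ImmR = 41.69, DelR = 8.92, Rec = 43.08),
    sds = c(Forward = 2.00, Backward = 2.13,
            ImmR = 9.71, DelR = 3.03, Rec = 3.74),
    correlation = 0.5) {
  stopifnot(inherits(config, "mw_synth_config"),
            identical(names(means), names(sds)),
            correlation >= 0, correlation < 1)
  n <- config$n_subjects
  set.seed((config$seed %% 100000L) * 20011L + 7L)
  z <- stats::rnorm(n)  # shared subject factor
  out <- data.frame(subject_id = sprintf("S%02d", seq_len(n)))
  for (s in names(means)) {
    e <- stats::rnorm(n)
    out[[s]] <- means[[s]] +
      sds[[s]] * (sqrt(correlation) * z + sqrt(1 - correlation) * e)
  }
  out
}
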