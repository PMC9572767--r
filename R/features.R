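#' @keywords internal
thermal_feature_names <- function()
  c("MeanTemp", "STD", "K", "S", "P90", "SampEn", "LF", "HF", "LFHF")

#' @keywords internal
hrv_feature_names <- function()
  c("RRmean", "SDNN", "RMSSD", "LF", "HF", "LFHF")

# Phases belonging to each cognitive task; BL is never a class.
task_phases <- function(task) {
  switch(task,
         DST = c("Forward", "Backward"),
         RAVLT = c("ImmR", "DelR", "Rec"),
         stop(sprintf("unknown task '%s'", task), call. = FALSE))
}

#' Class label for a task phase
#'
#' Two-level coding for the digit-span task (Forward = 0, Backward = 1) and
#' three-level coding for the verbal-learning task (ImmR = 0, DelR = 1,
#' Rec = 2). The baseline phase carries no class and raises an error.
#'
#' @param task `"DST"` or `"RAVLT"`.
#' @param phase phase label belonging to the task.
#' @return integer class label.
#' @export
label_for_phase <- function(task, phase) {
  phases <- task_phases(task)
  idx <- match(phase, phases)
  if (is.na(idx))
    stop(sprintf("phase '%s' does not belong to task %s", phase, task),
         call. = FALSE)
  idx - 1L
}

# Full preprocessing + descriptor extraction for one subject record.
extract_subject_features <- function(rec, phases, hampel, sampen, bands,
                                     ecg_params, log = NULL) {
  # thermal: Hampel first, then subtraction of the cleaned baseline mean
  bl_mean <- lapply(c(nosetip = "nosetip", glabella = "glabella"),
                    function(roi) {
                      bw <- hampel_filter(rec$baseline_thermal[[roi]],
                                          hampel)$series
                      mean(bw$values)
                    })
  thermal_rows <- list()
  for (roi in c("nosetip", "glabella")) {
    pref <- if (roi == "nosetip") "Nosetip" else "Glabella"
    for (ph in phases) {
      hf <- hampel_filter(rec$thermal[[roi]][[ph]], hampel)
      cleaned <- hf$series
      centered <- time_series(cleaned$values - bl_mean[[roi]],
                              fs = cleaned$fs, phase = ph, channel = roi)
      fv <- thermal_feature_vector(centered, sampen, bands)
      names(fv) <- paste(pref, names(fv), sep = "_")
      thermal_rows[[ph]] <- c(thermal_rows[[ph]], fv)
      if (!is.null(log))
        log(sprintf("%s %s %s: %d sample(s) replaced by Hampel",
                    rec$subject_id, roi, ph, sum(hf$outlier)))
    }
  }

  hrv_one <- function(ph) {
    if (is.null(rec$ecg[[ph]])) return(NULL)
    ecg <- suppressMessages(preprocess_ecg(rec$ecg[[ph]], ecg_params))
    beats <- detect_r_peaks(ecg, ecg_params)
    if (length(beats) < 4L) return(NULL)
    rr <- rr_from_peaks(beats, ecg$fs)
    c(hrv_time_features(rr), hrv_freq_features(rr, bands))
  }
  hrv_bl <- hrv_one("BL")
  hrv_rows <- lapply(phases, function(ph) {
    hp <- hrv_one(ph)
    if (is.null(hp) || is.null(hrv_bl)) {
      stats::setNames(rep(NA_real_, 6L),
                      paste("HRV", hrv_feature_names(), sep = "_"))
    } else {
      ratio <- normalize_to_baseline(hp, hrv_bl)
      stats::setNames(as.numeric(ratio),
                      paste("HRV", names(ratio), sep = "_"))
    }
  })
  names(hrv_rows) <- phases

  do.call(rbind, lapply(phases, function(ph) {
    data.frame(subject_id = rec$subject_id, phase = ph,
               t(thermal_rows[[ph]]), t(hrv_rows[[ph]]),
               check.names = FALSE)
  }))
}

#' Extract all features for a cohort
#'
#' Runs the full preprocessing chain for every subject and task phase:
#' thermal traces are Hampel-filtered and expressed relative to the cleaned
#' 60-s pre-task baseline mean, then reduced to the nine-descriptor vector
#' per ROI; ECG is band-pass/notch filtered, R peaks detected, and the six
#' HRV features computed and divided by their baseline-phase values.
#'
#' @param cohort an `mw_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param hampel,sampen,bands,ecg_params parameter objects; see
#'   [hampel_params()], [sampen_params()], [band_spec()],
#'   [ecg_preproc_params()].
#' @param phases which phases to extract (defaults to all task phases).
#' @param verbose log per-stage counts (Hampel replacements) via `message`.
#' @return a data.frame with `subject_id`, `phase`, 18 thermal columns
#'   (`Nosetip_*`, `Glabella_*`) and 6 HRV columns (`HRV_*`).
#' @export
extract_features <- function(cohort,
                             hampel = hampel_params(),
                             sampen = sampen_params(),
                             bands = band_spec(),
                             ecg_params = ecg_preproc_params(),
                             phases = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(cohort, "mw_cohort"))
  cfg <- attr(cohort, "config")
  if (is.null(phases)) phases <- setdiff(cfg$phases, "BL")
  log <- if (verbose) function(msg) message(msg) else NULL
  out <- do.call(rbind, lapply(cohort, function(rec) {
    suppressWarnings(
      extract_subject_features(rec, phases, hampel, sampen, bands,
                               ecg_params, log))
  }))
  rownames(out) <- NULL
  out
}

# View -> feature column names.
view_columns <- function(view) {
  th <- thermal_feature_names()
  switch(view,
         ir = c(paste0("Nosetip_", th), paste0("Glabella_", th)),
         hrv = paste0("HRV_", hrv_feature_names()),
         multimodal = c(paste0("Nosetip_", th), paste0("Glabella_", th),
                        paste0("HRV_", hrv_feature_names())),
         stop(sprintf("unknown view '%s' (use ir, hrv or multimodal)", view),
              call. = FALSE))
}

#' Assemble a labeled feature table for a task and modality view
#'
#' Builds the classifier input table: one row per subject per task phase,
#' with the class label implied by the phase and the feature columns of the
#' requested view (`"ir"`: 18 thermal features; `"hrv"`: 6 HRV ratios;
#' `"multimodal"`: all 24). Subjects missing any of the task's phases are
#' dropped with a warning. Rows are sorted by subject then phase, so a
#' complete cohort yields balanced classes.
#'
#' @param features either an `mw_cohort` (features are extracted with
#'   default parameters) or the data.frame returned by
#'   [extract_features()].
#' @param task `"DST"` or `"RAVLT"`.
#' @param view `"ir"`, `"hrv"` or `"multimodal"`.
#' @return an `mw_feature_table`: a data.frame with columns `subject_id`,
#'   `task`, `phase`, `label`, then the view's feature columns.
#' @export
assemble <- function(features, task, view = "multimodal") {
  if (inherits(features, "mw_cohort")) features <- extract_features(features)
  phases <- task_phases(task)
  cols <- view_columns(view)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0)
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- features[features$phase %in% phases, , drop = FALSE]
  keep_subjects <- character(0)
  for (sid in unique(sub$subject_id)) {
    have <- sub$phase[sub$subject_id == sid]
    if (all(phases %in% have)) keep_subjects <- c(keep_subjects, sid)
    else warning(sprintf("subject %s dropped: missing phase(s) %s", sid,
                         paste(setdiff(phases, have), collapse = ", ")),
                 call. = FALSE)
  }
  sub <- sub[sub$subject_id %in% keep_subjects, , drop = FALSE]
  ord <- order(sub$subject_id, match(sub$phase, phases))
  sub <- sub[ord, , drop = FALSE]
  out <- data.frame(
    subject_id = sub$subject_id,
    task = rep(task, nrow(sub)),
    phase = sub$phase,
    label = vapply(sub$phase, function(p) label_for_phase(task, p),
                   integer(1)),
    sub[, cols, drop = FALSE],
    check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("mw_feature_table", "data.frame"),
            task = task, view = view)
}

#' Feature columns of a feature table
#' @param table an `mw_feature_table`.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table)
  setdiff(names(table), c("subject_id", "task", "phase", "label"))

#' Drop rows with undefined feature values
#'
#' Removes rows containing any `NA` feature entry (no imputation), logging
#' how many removals each feature caused. Errors if nothing survives.
#'
#' @param table an `mw_feature_table`.
#' @return the filtered table.
#' @export
drop_incomplete <- function(table) {
  cols <- feature_columns(table)
  na_mat <- is.na(as.matrix(table[, cols, drop = FALSE]))
  bad <- rowSums(na_mat) > 0
  if (any(bad)) {
    per_feature <- colSums(na_mat)
    per_feature <- per_feature[per_feature > 0]
    message(sprintf("dropping %d row(s) with missing values (%s)",
                    sum(bad),
                    paste(sprintf("%s: %d", names(per_feature), per_feature),
                          collapse = ", ")))
  }
  out <- table[!bad, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("all rows contained missing values; inspect the extraction log",
         call. = FALSE)
  out
}

#' Write / read a feature table as CSV
#'
#' Plain-text round-trip of the classifier input table. The header is
#' `subject_id,task,phase,label` followed by the feature columns in their
#' fixed order.
#'
#' @param table an `mw_feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns an `mw_feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  structure(df, class = c("mw_feature_table", "data.frame"),
            task = df$task[1],
            view = if (all(startsWith(feature_columns(df), "HRV_"))) "hrv"
                   else if (any(startsWith(feature_columns(df), "HRV_")))
                     "multimodal" else "ir")
}
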