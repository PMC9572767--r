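#' Write a cohort to disk as plain CSV signals
#'
#' One file per subject / phase / channel with columns `time_s,value`, a
#' manifest CSV (`subject_id,phase,channel,path`) tying them together, and
#' a scores CSV when scores are supplied. This is the same layout
#' [read_cohort()] ingests, so synthetic data round-trip losslessly.
#'
#' @param cohort an `mw_cohort`.
#' @param dir output directory (created if needed).
#' @param scores optional data.frame from [generate_scores()].
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, scores = NULL) {
  stopifnot(inherits(cohort, "mw_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(ts, sid, ph, ch) {
    fn <- sprintf("%s_%s_%s.csv", sid, ph, ch)
    tt <- (seq_along(ts$values) - 1) / ts$fs
    utils::write.csv(data.frame(time_s = tt, value = ts$values),
                     file.path(dir, fn), row.names = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sid, phase = ph, channel = ch, path = fn)
  }
  for (rec in cohort) {
    for (roi in names(rec$thermal))
      for (ph in names(rec$thermal[[roi]]))
        emit(rec$thermal[[roi]][[ph]], rec$subject_id, ph, roi)
    for (ph in names(rec$ecg))
      emit(rec$ecg[[ph]], rec$subject_id, ph, "ecg")
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  if (!is.null(scores))
    utils::write.csv(scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a signal manifest
#'
#' Rebuilds subject records from the CSV layout written by
#' [write_cohort()] (or prepared by hand for real recordings). Sampling
#' rates are inferred from the time column; the 60-s thermal baseline
#' window is carved from the end of each subject's `BL` trace.
#'
#' @param manifest_path path to the manifest CSV.
#' @return an `mw_cohort` (without simulation ground truth).
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path,
                              colClasses = c(subject_id = "character"))
  base <- dirname(manifest_path)
  read_sig <- function(row) {
    path <- file.path(base, row$path)
    df <- tryCatch(utils::read.csv(path), error = function(e)
      stop(sprintf("malformed signal CSV '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
    if (!all(c("time_s", "value") %in% names(df)) || nrow(df) < 2)
      stop(sprintf("malformed signal CSV '%s': need columns time_s,value",
                   path), call. = FALSE)
    fs <- 1 / stats::median(diff(df$time_s))
    time_series(df$value, fs = round(fs, 6), phase = row$phase,
                channel = row$channel)
  }
  phases <- unique(manifest$phase)
  phases <- c(intersect("BL", phases), setdiff(phases, "BL"))
  records <- lapply(unique(manifest$subject_id), function(sid) {
    sub <- manifest[manifest$subject_id == sid, , drop = FALSE]
    rec <- list(subject_id = sid,
                thermal = list(nosetip = list(), glabella = list()),
                ecg = list(), baseline_thermal = list())
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, , drop = FALSE]
      ts <- read_sig(row)
      if (row$channel == "ecg") rec$ecg[[row$phase]] <- ts
      else rec$thermal[[row$channel]][[row$phase]] <- ts
    }
    for (roi in names(rec$thermal))
      if (!is.null(rec$thermal[[roi]][["BL"]]))
        rec$baseline_thermal[[roi]] <- tail_window(rec$thermal[[roi]]$BL, 60)
    structure(rec, class = "mw_subject")
  })
  names(records) <- unique(manifest$subject_id)
  cfg <- list(phases = phases, n_subjects = length(records))
  structure(records, class = "mw_cohort", config = cfg)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param with_scores also generate and write cognitive-test scores.
#' @return the manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir, with_scores = TRUE) {
  cohort <- generate_cohort(config)
  scores <- if (with_scores) generate_scores(config) else NULL
  write_cohort(cohort, out_dir, scores = scores)
}

#' Extract feature tables from a signal manifest
#'
#' Reads the cohort, runs the full thermal and cardiac extraction and
#' writes one feature-table CSV per task and view
#' (`features_<task>_<view>.csv`). Subjects without usable ECG keep their
#' thermal rows (the HRV columns become `NA` and those rows are dropped
#' only from HRV-containing views).
#'
#' @param manifest_path manifest CSV path (or an `mw_cohort` directly).
#' @param out_dir output directory for the tables.
#' @param tasks,views which tables to emit.
#' @param hampel,sampen,bands,ecg_params extraction parameters.
#' @param verbose log per-stage counts.
#' @return named list of written file paths, invisibly.
#' @export
run_extract <- function(manifest_path, out_dir,
                        tasks = c("DST", "RAVLT"),
                        views = c("ir", "hrv", "multimodal"),
                        hampel = hampel_params(),
                        sampen = sampen_params(),
                        bands = band_spec(),
                        ecg_params = ecg_preproc_params(),
                        verbose = FALSE) {
  cohort <- if (inherits(manifest_path, "mw_cohort")) manifest_path
            else read_cohort(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- extract_features(cohort, hampel = hampel, sampen = sampen,
                            bands = bands, ecg_params = ecg_params,
                            verbose = verbose)
  paths <- list()
  for (task in tasks) {
    for (view in views) {
      tab <- assemble(feats, task, view)
      tab <- tryCatch(suppressMessages(drop_incomplete(tab)),
                      error = function(e) tab)
      p <- file.path(out_dir, sprintf("features_%s_%s.csv", task, view))
      write_feature_table(tab, p)
      paths[[sprintf("%s_%s", task, view)]] <- p
      if (verbose)
        message(sprintf("wrote %s (%d rows)", p, nrow(tab)))
    }
  }
  invisible(paths)
}

#' Cross-validated accuracy grid over presets, views and tasks
#'
#' Mirrors the standard summary layout for this analysis: one row per
#' classifier preset, one column per (view, task) combination, each cell
#' the mean pooled subject-grouped CV accuracy (in %) over `repetitions`
#' shuffled fold plans. Logistic regression on the three-class task is
#' reported as `NA` with the note "not applicable (binary-only)". Full
#' evaluation reports (confusion matrix, ROC/AUC) are returned for the
#' best preset of each column.
#'
#' @param tables named list of `mw_feature_table`s (or file paths),
#'   names like `"DST_ir"`.
#' @param presets data.frame of `family` / `preset` rows (defaults to all
#'   sixteen).
#' @param k folds.
#' @param repetitions shuffled-plan repetitions per cell.
#' @param seed base seed.
#' @return an object of class `mw_grid`: list with `accuracy` (data.frame,
#'   % units), `notes`, and `best_reports` (per column).
#' @export
run_evaluate <- function(tables, presets = model_presets(), k = 5L,
                         repetitions = 5L, seed = 1L) {
  tables <- lapply(tables, function(t)
    if (is.character(t)) read_feature_table(t) else t)
  cols <- names(tables)
  grid <- data.frame(family = presets$family, preset = presets$preset)
  notes <- character(0)
  best_reports <- list()
  for (cn in cols) {
    tab <- tables[[cn]]
    task <- attr(tab, "task")
    cell <- rep(NA_real_, nrow(presets))
    for (i in seq_len(nrow(presets))) {
      if (presets$family[i] == "logistic_regression" && task == "RAVLT") {
        notes <- c(notes, sprintf(
          "%s / logistic_regression: not applicable (binary-only)", cn))
        next
      }
      spec <- model_spec(presets$family[i], presets$preset[i], seed = seed)
      cell[i] <- suppressWarnings(
        repeat_cv(spec, tab, repetitions = repetitions, k = k,
                  seed = seed)$mean_accuracy)
    }
    grid[[cn]] <- 100 * cell
    best <- which.max(cell)
    spec <- model_spec(presets$family[best], presets$preset[best],
                       seed = seed)
    plan <- make_group_folds(unique(tab$subject_id), k = k, seed = seed)
    cv <- suppressWarnings(cross_validate(spec, tab, plan))
    best_reports[[cn]] <- list(
      family = presets$family[best], preset = presets$preset[best],
      report = evaluation_report(cv$predictions))
  }
  structure(list(accuracy = grid, notes = unique(notes),
                 best_reports = best_reports),
            class = "mw_grid")
}

#' @export
print.mw_grid <- function(x, ...) {
  df <- x$accuracy
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 1)
  print(df, row.names = FALSE)
  if (length(x$notes) > 0) cat(paste0(x$notes, collapse = "\n"), "\n")
  invisible(x)
}
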