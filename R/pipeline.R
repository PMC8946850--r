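#' Decimation grid used for evaluation (seconds)
#' @export
DECIMATIONS <- c(1, 10, 20, 30, 40, 50, 60)

#' Process all sessions of one subject into per-epoch stress features
#'
#' Fixed pipeline order for the EEG: band-pass filter, blink correction,
#' 1 s epoching, amplitude artifact rejection, band power. The IAF is
#' estimated from the eyes-closed rest block and anchors the subject's
#' high-beta band. The EDA of every task session is preprocessed, spike
#' corrected and decomposed, yielding the per-epoch mean SCL.
#'
#' @param sessions list of `recording_session` objects of one subject (as
#'   returned by [generate_subject()] or [read_sessions()]).
#' @param reject_threshold epoch rejection ceiling in microvolts.
#' @param blink_threshold blink detection threshold in microvolts.
#' @param causal logical; use causal filtering.
#' @return object of class `processed_subject`: the IAF estimate, the band
#'   definition, one feature table per task session (epoch-wise P3/P4 band
#'   power, Neurometric value, SCL, condition, block and repetition ids)
#'   and the overall rejected-epoch fraction.
#' @export
process_subject <- function(sessions, reject_threshold = 80,
                            blink_threshold = 40, causal = FALSE) {
  tasks <- vapply(sessions, function(s) s$task, character(1))
  rest_i <- which(tasks == "rest")
  if (length(rest_i) == 0) stop("a rest session is required for the IAF")
  rest <- bandpass_filter(sessions[[rest_i[1]]]$eeg, causal = causal)
  iaf <- estimate_iaf(rest)
  band <- beta_high_band(iaf)

  tabs <- list()
  n_flagged <- 0L; n_total <- 0L
  run_counter <- 0L
  for (s in sessions) {
    if (s$task == "rest") next
    run_counter <- run_counter + 1L
    blk <- bandpass_filter(s$eeg, causal = causal)
    blk <- remove_blinks(blk, threshold = blink_threshold)
    ep <- epoch_signal(blk, 1, condition = s$condition)
    ep <- reject_artifacts(ep, reject_threshold)
    n_flagged <- n_flagged + sum(ep$artifact_flags)
    n_total <- n_total + length(ep$artifact_flags)
    fs <- band_power(ep, band)

    dur <- ncol(s$eeg$samples) / s$eeg$sampling_rate
    all_windows <- cbind(0:(floor(dur) - 1), 1:floor(dur))
    eda_p <- preprocess_eda(s$eda)
    eda_c <- correct_spikes(eda_p)
    dec <- decompose_eda(eda_c$trace)
    scl_all <- mean_scl(dec$tonic, all_windows)

    kept <- match(round(fs$epoch_times), round(all_windows[, 1]))
    tab <- data.frame(
      epoch_time = fs$epoch_times,
      P3 = fs$values[, "P3"], P4 = fs$values[, "P4"],
      neurometric = rowMeans(fs$values[, c("P3", "P4"), drop = FALSE]),
      scl = scl_all$value[kept],
      condition = fs$condition,
      task = s$task,
      level = s$level,
      scenario = s$scenario,
      repetition_id = s$repetition_id,
      run = run_counter,
      stringsAsFactors = FALSE)
    tabs[[length(tabs) + 1L]] <- tab
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  structure(list(subject_id = sessions[[rest_i[1]]]$subject_id,
                 iaf = iaf, band = band, epochs = tab,
                 rejected_fraction = n_flagged / n_total),
            class = "processed_subject")
}

#' @export
print.processed_subject <- function(x, ...) {
  cat(sprintf("<processed_subject %s> IAF %.2f Hz, %d epochs, %.1f%% rejected\n",
              x$subject_id, x$iaf$iaf, nrow(x$epochs),
              100 * x$rejected_fraction))
  invisible(x)
}

task_rows <- function(proc, task) {
  if (task == "multitask") grepl("^multitask", proc$epochs$task)
  else proc$epochs$task == "driving_run"
}

#' Evaluation score series of a calibration-free measure
#'
#' Builds one [score_series()] per repetition for the Neurometric or SCL
#' measure: labeled epochs only (multitask levels 1-2 and 6-7, or the
#' low/high driving runs), with condition blocks that the decimation stage
#' respects.
#'
#' @param proc a [process_subject()] result.
#' @param measure `"neurometric"` or `"scl"`.
#' @param task `"multitask"` or `"driving"`.
#' @return named list of `score_series`, one per repetition.
#' @export
measure_scores <- function(proc, measure = c("neurometric", "scl"),
                           task = c("multitask", "driving")) {
  measure <- match.arg(measure)
  task <- match.arg(task)
  e <- proc$epochs[task_rows(proc, task), , drop = FALSE]
  lab <- condition_to_label(e$condition)
  e <- e[!is.na(lab), , drop = FALSE]
  out <- list()
  for (r in sort(unique(e$repetition_id))) {
    er <- e[e$repetition_id == r, , drop = FALSE]
    out[[as.character(r)]] <- score_series(
      er[[measure]], epoch_times = er$epoch_time,
      labels = condition_to_label(er$condition),
      blocks = er$run, measure = measure, subject_id = proc$subject_id)
  }
  out
}

#' Labeled random-forest feature set for one task
#'
#' @param proc a [process_subject()] result.
#' @param task `"multitask"` or `"driving"`.
#' @return list with the [labeled_feature_set()] and the matching
#'   `epoch_info` data frame (`epoch_time`, `block`).
#' @export
task_features <- function(proc, task = c("multitask", "driving")) {
  task <- match.arg(task)
  e <- proc$epochs[task_rows(proc, task), , drop = FALSE]
  lab <- condition_to_label(e$condition)
  e <- e[!is.na(lab), , drop = FALSE]
  lfs <- labeled_feature_set(e, subject_id = proc$subject_id)
  list(data = lfs,
       epoch_info = data.frame(epoch_time = e$epoch_time, block = e$run))
}

#' Per-subject AUC across decimations for one measure
#'
#' AUC is computed per evaluation session (repetition) after moving-average
#' decimation, then averaged across sessions.
#'
#' @param series_list list of [score_series()] (one per session).
#' @param decimations vector of window lengths in seconds.
#' @return named numeric vector of AUCs, one per decimation.
#' @export
subject_auc <- function(series_list, decimations = DECIMATIONS) {
  vapply(decimations, function(w) {
    mean(vapply(series_list, function(s)
      compute_auc(moving_average_decimate(s, w)), numeric(1)))
  }, numeric(1)) |> stats::setNames(as.character(decimations))
}

#' Run the full synthetic study
#'
#' Generates a cohort, runs every pipeline and assembles the AUC arrays for
#' the requested measures, tasks and decimations. Subjects whose
#' rejected-epoch fraction exceeds `quota` are excluded from the cohort
#' statistics.
#'
#' @param n_subjects cohort size (before exclusion).
#' @param seed master seed; subject seeds are derived as
#'   `(seed - 1) * 1000 + 1:n_subjects`.
#' @param beta_effect standardized high-beta stress effect passed to every
#'   subject's configuration.
#' @param measures subset of `"neurometric"`, `"scl"`, `"rf_intra"`,
#'   `"rf_cross"` (the latter applies to driving only).
#' @param tasks subset of `"multitask"`, `"driving"`.
#' @param decimations decimation grid in seconds.
#' @param rf_budget randomized-search budget for the forest comparators.
#' @param quota maximum tolerated rejected-epoch fraction.
#' @param config_args named list of further [subject_config()] arguments.
#' @param keep_scores logical; retain the per-subject score series (for
#'   curve comparison).
#' @return object of class `stress_study`: per-task AUC arrays
#'   (retained subjects x measures x decimations), the IAF table,
#'   excluded subject ids, and optionally the score series.
#' @export
run_study <- function(n_subjects = 18, seed = 1, beta_effect = 1.5,
                      measures = c("neurometric", "scl"),
                      tasks = c("multitask", "driving"),
                      decimations = DECIMATIONS,
                      rf_budget = 10, quota = 0.3,
                      config_args = list(), keep_scores = FALSE) {
  subject_seeds <- (seed - 1) * 1000 + seq_len(n_subjects)
  auc <- list()
  for (tk in tasks) {
    ms <- if (tk == "driving") measures else setdiff(measures, "rf_cross")
    auc[[tk]] <- array(NA_real_,
                       dim = c(n_subjects, length(ms), length(decimations)),
                       dimnames = list(NULL, ms, as.character(decimations)))
  }
  iafs <- data.frame(subject = character(0), iaf_true = numeric(0),
                     iaf_est = numeric(0), rejected = numeric(0))
  scores <- list()
  excluded <- character(0)

  for (i in seq_len(n_subjects)) {
    cfg <- do.call(subject_config, c(list(
      subject_id = sprintf("S%02d", i), seed = subject_seeds[i],
      beta_effect = beta_effect), config_args))
    proc <- process_subject(generate_subject(cfg))
    iafs <- rbind(iafs, data.frame(subject = cfg$subject_id,
                                   iaf_true = cfg$iaf_true,
                                   iaf_est = proc$iaf$iaf,
                                   rejected = proc$rejected_fraction))
    if (proc$rejected_fraction > quota) {
      excluded <- c(excluded, cfg$subject_id)
      next
    }
    subj_scores <- list()
    for (tk in tasks) {
      sers <- list()
      for (m in intersect(measures, c("neurometric", "scl")))
        sers[[m]] <- measure_scores(proc, m, tk)
      if ("rf_intra" %in% measures) {
        tf <- task_features(proc, tk)
        sers$rf_intra <- intra_subject_protocol(
          tf$data, model_spec(search_budget = rf_budget,
                              seed = subject_seeds[i]),
          epoch_info = tf$epoch_info)
      }
      if ("rf_cross" %in% measures && tk == "driving") {
        mt <- task_features(proc, "multitask")
        dr <- task_features(proc, "driving")
        sers$rf_cross <- list(cross_task_protocol(
          mt$data, dr$data, model_spec(search_budget = rf_budget,
                                       seed = subject_seeds[i]),
          epoch_info = dr$epoch_info))
      }
      for (m in names(sers))
        auc[[tk]][i, m, ] <- subject_auc(sers[[m]], decimations)
      if (keep_scores) subj_scores[[tk]] <- sers
    }
    if (keep_scores) scores[[cfg$subject_id]] <- subj_scores
  }

  retained <- setdiff(iafs$subject, excluded)
  keep <- iafs$subject %in% retained
  for (tk in tasks) auc[[tk]] <- auc[[tk]][keep, , , drop = FALSE]
  structure(list(auc = auc, iaf = iafs, retained = retained,
                 excluded = excluded, decimations = decimations,
                 scores = if (keep_scores) scores else NULL),
            class = "stress_study")
}

#' @export
print.stress_study <- function(x, ...) {
  cat(sprintf("<stress_study> %d retained subjects (%d excluded)\n",
              length(x$retained), length(x$excluded)))
  for (tk in names(x$auc)) {
    cat(sprintf("  %s: mean AUC at %s s decimation\n", tk,
                utils::tail(colnames(x$auc[[tk]][1, , , drop = TRUE]), 1)))
    m <- apply(x$auc[[tk]], c(2, 3), mean)
    print(round(m, 3))
  }
  invisible(x)
}

#' Subject-averaged AUC of one measure
#'
#' @param study a [run_study()] result.
#' @param task `"multitask"` or `"driving"`.
#' @param measure measure name.
#' @param decimation decimation in seconds.
#' @return mean AUC across retained subjects.
#' @export
mean_auc <- function(study, task, measure, decimation) {
  mean(study$auc[[task]][, measure, as.character(decimation)])
}
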