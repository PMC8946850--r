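#' Write recording sessions to plain-text files
#'
#' One directory per subject: per-session EEG CSV (channels as columns,
#' header row of channel names), EDA CSV (time, microsiemens), behavior CSV
#' where present, and a `manifest.csv` tying subject, task, condition,
#' repetition and file paths together.
#'
#' @param sessions list of `recording_session` objects.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_sessions <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    base <- sprintf("%s_%02d_%s", s$subject_id, i, s$task)
    eeg_f <- paste0(base, "_eeg.csv")
    eda_f <- paste0(base, "_eda.csv")
    eeg <- as.data.frame(t(s$eeg$samples))
    names(eeg) <- s$eeg$channel_names
    utils::write.csv(eeg, file.path(dir, eeg_f), row.names = FALSE)
    eda <- data.frame(
      time = seq_along(s$eda$samples) / s$eda$sampling_rate,
      microsiemens = s$eda$samples)
    utils::write.csv(eda, file.path(dir, eda_f), row.names = FALSE)
    beh_f <- NA_character_
    if (inherits(s$behavior, "collision_log")) {
      beh_f <- paste0(base, "_events.csv")
      utils::write.csv(as.data.frame(s$behavior), file.path(dir, beh_f),
                       row.names = FALSE)
    }
    manifest <- rbind(manifest, data.frame(
      subject = s$subject_id, task = s$task, condition = s$condition,
      repetition_id = s$repetition_id, scenario = s$scenario,
      level = s$level, eeg_fs = s$eeg$sampling_rate,
      eda_fs = s$eda$sampling_rate,
      eeg_file = eeg_f, eda_file = eda_f, behavior_file = beh_f,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read recording sessions written by [write_sessions()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list of `recording_session` objects (behavior logs are restored
#'   for driving runs; multitask behavior is not round-tripped).
#' @export
read_sessions <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    r <- mf[i, ]
    eeg <- utils::read.csv(file.path(dir, r$eeg_file), check.names = FALSE)
    blk <- eeg_block(t(as.matrix(eeg)), r$eeg_fs, names(eeg))
    eda <- utils::read.csv(file.path(dir, r$eda_file))
    tr <- eda_trace(eda$microsiemens, r$eda_fs, "raw")
    beh <- NULL
    if (!is.na(r$behavior_file)) {
      log <- utils::read.csv(file.path(dir, r$behavior_file),
                             stringsAsFactors = FALSE)
      beh <- structure(log, class = c("collision_log", "data.frame"),
                       condition = r$condition)
    }
    recording_session(r$subject, r$task, r$condition, blk, tr, beh,
                      r$repetition_id, r$scenario, r$level)
  })
}

#' Export a score series as CSV
#'
#' Columns: epoch_time, value, label, block, measure, subject.
#'
#' @param series a [score_series()].
#' @param file output path.
#' @export
write_scores <- function(series, file) {
  df <- as.data.frame(series)
  df$measure <- attr(series, "measure")
  df$subject <- attr(series, "subject_id")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
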