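#' Multitask performance indices
#'
#' Four per-subtask indices on a 0-100 scale and their average. All of them
#' are increasing in "goodness": more right answers, shorter reaction times.
#'
#' @param record a `performance_record` (see [generate_behavior()]).
#' @return percentage in `[0, 100]`.
#' @name performance_indices
NULL

#' @describeIn performance_indices Mental arithmetic:
#'   `100 * num_right_additions / max_num_additions`, where the maximum is
#'   the subject's largest number of additions across the seven levels.
#' @export
arithmetic_index <- function(record) {
  if (record$max_num_additions <= 0) stop("max_num_additions must be > 0")
  100 * record$num_right_additions / record$max_num_additions
}

#' @describeIn performance_indices Auditory monitoring: mean over answers of
#'   `100 * (5 - ReactionTime) / 5`; wrong answers carry `ReactionTime = 5`
#'   (the inter-stimulus interval), so they score 0.
#' @export
auditory_index <- function(record) {
  rt <- record$auditory_reaction_times
  if (length(rt) == 0) stop("no auditory answers")
  if (any(rt < 0 | rt > 5)) stop("reaction times must lie in [0, 5]")
  mean(100 * (5 - rt) / 5)
}

#' @describeIn performance_indices Visual monitoring: mean over events of
#'   `100 - (Bar2Fill + 100 * ReactionTime / Time2Fill)`, clipped to
#'   `[0, 100]`. `Time2Fill : 100 = ReactionTime : BarEquivalent` converts
#'   the reset delay into bar-percentage units.
#' @export
visual_index <- function(record) {
  ev <- record$visual_events
  if (nrow(ev) == 0) stop("no visual events")
  if (any(ev$time2fill <= 0)) stop("Time2Fill must be positive")
  raw <- 100 - (ev$bar2fill + 100 * ev$reaction_time / ev$time2fill)
  mean(pmin(pmax(raw, 0), 100))
}

#' @describeIn performance_indices Phone number entry:
#'   `100 * num_right_entries / max_num_entries`.
#' @export
phone_index <- function(record) {
  if (record$max_num_entries <= 0) stop("max_num_entries must be > 0")
  100 * record$num_right_entries / record$max_num_entries
}

#' @describeIn performance_indices Overall index: arithmetic mean of the
#'   four subtask indices.
#' @export
overall_index <- function(record) {
  mean(c(arithmetic_index(record), auditory_index(record),
         visual_index(record), phone_index(record)))
}

#' Count collisions in a driving simulator event log
#'
#' Only events with `event_type == "collision"` are counted; other logged
#' events (waypoints etc.) are ignored.
#'
#' @param log a `collision_log` data frame with columns `time`,
#'   `event_type`, `object`.
#' @return integer collision count.
#' @export
count_collisions <- function(log) {
  req <- c("time", "event_type", "object")
  if (!all(req %in% names(log))) stop("malformed collision log")
  bad <- which(!is.finite(log$time) | is.na(log$event_type))
  if (length(bad) > 0)
    stop(sprintf("malformed log line %d", bad[1]))
  sum(log$event_type == "collision")
}
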