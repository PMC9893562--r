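#' Segment switch closures into running bouts
#'
#' The behavioral micro-analysis breaks wheel running into bouts at pauses:
#' an inter-closure interval greater than `pause_s` ends the current bout and
#' the next closure starts a new one. The comparison is strict, so an interval
#' of exactly `pause_s` stays within the bout. Every closure counts as one
#' revolution and belongs to exactly one bout; a bout can consist of a single
#' closure, in which case its duration is zero and its rate undefined.
#'
#' @param timestamps Non-decreasing numeric vector of closure times
#'   (seconds since midnight).
#' @param pause_s Bout-break pause criterion in seconds. Default 9.
#' @param geometry A [wheel_geometry()] used for per-bout distance.
#'
#' @return A data frame with one row per bout: `start_s`, `end_s`,
#'   `revolutions`, `duration_s`, `rate_rev_per_s` (`NA` for single-closure
#'   bouts) and `distance_m`.
#' @examples
#' segment_bouts(c(0, 3, 6, 20, 22))
#' @export
segment_bouts <- function(timestamps, pause_s = 9, geometry = wheel_geometry()) {
  if (!is.numeric(pause_s) || length(pause_s) != 1L || !is.finite(pause_s) ||
      pause_s < 0) {
    stop("`pause_s` must be a single non-negative number", call. = FALSE)
  }
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) && any(diff(timestamps) < 0)) {
    stop("`timestamps` must be non-decreasing", call. = FALSE)
  }
  if (!length(timestamps)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      revolutions = integer(), duration_s = numeric(),
                      rate_rev_per_s = numeric(), distance_m = numeric()))
  }
  breaks <- which(diff(timestamps) > pause_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(timestamps))
  rev <- ends - starts + 1L
  dur <- timestamps[ends] - timestamps[starts]
  data.frame(
    start_s = timestamps[starts],
    end_s = timestamps[ends],
    revolutions = rev,
    duration_s = dur,
    rate_rev_per_s = ifelse(dur > 0, rev / dur, NA_real_),
    distance_m = distance_from_revolutions(rev, geometry)
  )
}

#' Daily running metrics from one event stream
#'
#' Aggregates the bout decomposition of one animal-day into the standard
#' micro-analysis metrics: total distance, number of runs (bouts/day), run
#' length (median revolutions per bout), distance per run (median meters per
#' bout), and the pooled daily running rate — total in-bout revolutions
#' divided by total in-bout duration, over multi-closure bouts only, so that
#' zero-duration single-closure bouts neither crash nor distort the rate.
#' A zero-activity day yields all-zero metrics (the undefined rate is
#' reported as 0).
#'
#' @param stream An [event_stream()] (or a bare numeric timestamp vector).
#' @param geometry A [wheel_geometry()].
#' @param pause_s Bout pause criterion, seconds.
#' @param bout_summary How run length / distance-per-run summarize bouts:
#'   `"median"` (default) or `"mean"`.
#'
#' @return One-row data frame with `animal_id`, `day_date`, `age_days`,
#'   `total_revolutions`, `total_distance_m`, `n_runs`, `run_length_rev`,
#'   `distance_per_run_m`, `rate_rev_per_s`.
#' @export
daily_metrics <- function(stream, geometry = wheel_geometry(), pause_s = 9,
                          bout_summary = c("median", "mean")) {
  bout_summary <- match.arg(bout_summary)
  summarize <- if (bout_summary == "median") stats::median else mean
  if (is.numeric(stream)) {
    stream <- event_stream("unknown", Sys.Date(), stream)
  }
  stopifnot(inherits(stream, "event_stream"))
  bouts <- segment_bouts(stream$timestamps, pause_s = pause_s,
                         geometry = geometry)
  n <- nrow(bouts)
  if (n == 0L) {
    total_rev <- 0L; dist <- 0; runlen <- 0; dpr <- 0; rate <- 0
  } else {
    total_rev <- sum(bouts$revolutions)
    dist <- distance_from_revolutions(total_rev, geometry)
    runlen <- summarize(bouts$revolutions)
    dpr <- summarize(bouts$distance_m)
    multi <- bouts$duration_s > 0
    rate <- if (any(multi)) {
      sum(bouts$revolutions[multi]) / sum(bouts$duration_s[multi])
    } else 0
  }
  data.frame(
    animal_id = stream$animal_id,
    day_date = stream$day_date,
    age_days = stream$age_days,
    total_revolutions = as.integer(total_rev),
    total_distance_m = dist,
    n_runs = n,
    run_length_rev = runlen,
    distance_per_run_m = dpr,
    rate_rev_per_s = rate,
    stringsAsFactors = FALSE
  )
}

#' Daily metrics for a whole cohort
#'
#' Convenience wrapper: applies [daily_metrics()] to each stream and binds
#' the rows into one tidy table (one row per observed animal-day).
#'
#' @param streams List of [event_stream()] objects, e.g. from
#'   [read_cohort_days()].
#' @inheritParams daily_metrics
#' @return Data frame of per-animal-day metrics.
#' @export
daily_metrics_table <- function(streams, geometry = wheel_geometry(),
                                pause_s = 9,
                                bout_summary = c("median", "mean")) {
  bout_summary <- match.arg(bout_summary)
  rows <- lapply(streams, daily_metrics, geometry = geometry,
                 pause_s = pause_s, bout_summary = bout_summary)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
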