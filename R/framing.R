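#' Optimal time-window length
#'
#' The optimal number of records per time window is the size of the temporal
#' smoothing window: `ceiling(temporal_span * n)`. A span of 0.1 on 10,000
#' records gives windows of 1,000 records.
#'
#' @param n dataset size (records).
#' @param temporal_span AIC-optimal span of the whole-dataset temporal GAM.
#' @export
optimal_window_length <- function(n, temporal_span) {
  stopifnot(n >= 1)
  check_span(temporal_span)
  as.integer(ceiling(temporal_span * n))
}

# internal constructor; indices must be a contiguous run of dataset rows
new_window <- function(data, from, to, window_id = NA_integer_) {
  idx <- from:to
  len <- length(idx)
  days <- data$day[idx]
  structure(list(indices = idx,
                 first_day = days[1], last_day = days[len],
                 median_day = days[floor((len + 1) / 2)],
                 length = len, window_id = window_id),
            class = "ed_window")
}

#' @export
print.ed_window <- function(x, ...) {
  cat(sprintf("time window%s: %d records, days %d-%d, median day %d\n",
              if (is.na(x$window_id)) "" else paste0(" ", x$window_id),
              x$length, x$first_day, x$last_day, x$median_day))
  invisible(x)
}

#' First time window
#'
#' Records 1..L, extended forward to the end of the L-th record's calendar
#' day: a day is never split across a window boundary, so the window length
#' can exceed L (the planned length is a minimum).
#'
#' @param data an [ed_dataset()].
#' @param L minimum window length in records.
#' @return an `ed_window`.
#' @export
first_window <- function(data, L) {
  n <- nrow(data)
  if (L > n) stop("window length ", L, " exceeds dataset size ", n, call. = FALSE)
  last_day <- data$day[L]
  to <- max(which(data$day == last_day))
  new_window(data, 1L, to, window_id = 1L)
}

#' Day of a window's median record
#'
#' The day of record `floor((length + 1) / 2)` within the window (record 500
#' of a 1,000-record window).
#'
#' @param window an `ed_window`.
#' @export
window_median_day <- function(window) {
  stopifnot(inherits(window, "ed_window"))
  window$median_day
}

#' Interval in days between consecutive window median days
#'
#' Computed once, from the first window: `m = ceiling(window_span * length)`;
#' the interval is the relative day of the window's m-th record, where the
#' window's first day counts as relative day 1. A first-window span of 0.3 on
#' 1,000 records selects record 300; if record 300 falls on relative day 25,
#' the interval is 25 days.
#'
#' @param data the [ed_dataset()] the window indexes into.
#' @param window an `ed_window` (normally the first window).
#' @param window_span AIC-optimal span of the temporal GAM fitted to this
#'   window alone.
#' @export
inter_window_interval <- function(data, window, window_span) {
  check_span(window_span)
  m <- ceiling(window_span * window$length)
  rec_day <- data$day[window$indices[m]]
  max(1L, as.integer(rec_day - window$first_day + 1L))
}

#' Construct the window centred on a target median day
#'
#' Starts from all records on the target day (or, if that day has none, the
#' nearest populated day) and repeatedly annexes the entire nearer adjacent
#' unconsumed day — earlier wins ties — until at least `L` records are
#' included. Whole-day granularity and record contiguity hold by construction.
#'
#' @param data an [ed_dataset()].
#' @param target_median_day study day the window should be centred on.
#' @param L minimum number of records.
#' @param window_id sequence number to stamp on the window.
#' @export
next_window <- function(data, target_median_day, L, window_id = NA_integer_) {
  n <- nrow(data)
  if (L > n) stop("fewer than L = ", L, " records in the dataset", call. = FALSE)
  days_u <- unique(data$day)                  # sorted: data is day-sorted
  counts <- tabulate(match(data$day, days_u))
  nd <- length(days_u)
  t <- target_median_day
  if (t < days_u[1] || t > days_u[nd])
    stop("target median day ", t, " outside the dataset day range", call. = FALSE)
  pos <- which(days_u == t)
  if (length(pos)) {
    lo <- hi <- pos
    total <- counts[pos]
  } else {
    below <- which(days_u < t)
    above <- which(days_u > t)
    dl <- if (length(below)) t - days_u[max(below)] else Inf
    dr <- if (length(above)) days_u[min(above)] - t else Inf
    lo <- hi <- if (dl <= dr) max(below) else min(above)  # tie -> earlier
    total <- counts[lo]
  }
  while (total < L) {
    dl <- if (lo > 1L) t - days_u[lo - 1L] else Inf
    dr <- if (hi < nd) days_u[hi + 1L] - t else Inf
    if (!is.finite(dl) && !is.finite(dr))
      stop("cannot reach window length ", L, call. = FALSE)
    if (dl <= dr) { lo <- lo - 1L; total <- total + counts[lo] }
    else          { hi <- hi + 1L; total <- total + counts[hi] }
  }
  from <- match(days_u[lo], data$day)
  to <- from + sum(counts[lo:hi]) - 1L
  new_window(data, from, to, window_id)
}

#' Divide a dataset into overlapping time windows
#'
#' The full framing algorithm: the first window holds the first `L =
#' ceiling(temporal_span * n)` records (whole days); the interval between
#' median days is computed once from the first window via `window_span`;
#' subsequent windows are grown around target median days spaced by that
#' interval; the series stops with the first window whose last day is the
#' dataset's last day. If the planned median days would overshoot the study
#' period before any window touches the last day, the final target is clamped
#' to the last day so a closing window is always emitted.
#'
#' @param data an [ed_dataset()].
#' @param temporal_span span of the whole-dataset temporal GAM (select with
#'   [select_span()] or supply directly).
#' @param window_span span of the first window's temporal GAM.
#' @return object of class `ed_framing`: list of `ed_window`s plus the plan
#'   (`L`, `interval`, `median_days` planned, the spans).
#' @examples
#' cfg <- synthetic_config(n_records = 1000, study_days = 100, seed = 3)
#' d <- generate_dataset(cfg)
#' fr <- build_framing(d, temporal_span = 0.2, window_span = 0.5)
#' fr
#' @export
build_framing <- function(data, temporal_span, window_span) {
  if (!inherits(data, "ed_dataset")) data <- ed_dataset(data)
  L <- optimal_window_length(nrow(data), temporal_span)
  w1 <- first_window(data, L)
  interval <- inter_window_interval(data, w1, window_span)
  last_day <- data$day[nrow(data)]
  windows <- list(w1)
  planned <- window_median_day(w1)
  target <- planned
  id <- 1L
  while (windows[[length(windows)]]$last_day < last_day) {
    target <- target + interval
    clamped <- target > last_day
    if (clamped) target <- last_day
    id <- id + 1L
    planned <- c(planned, target)
    windows[[id]] <- next_window(data, target, L, window_id = id)
    if (clamped) break
  }
  structure(list(windows = windows,
                 plan = list(L = L, interval = interval,
                             median_days = planned,
                             temporal_span = temporal_span,
                             window_span = window_span)),
            class = "ed_framing")
}

#' @export
print.ed_framing <- function(x, ...) {
  p <- x$plan
  cat(sprintf("overlapping time windows: %d window(s), minimum length %d records, interval %d day(s)\n",
              length(x$windows), p$L, p$interval))
  cat(sprintf("spans: temporal %.3g (whole set), %.3g (first window); planned median days %s\n",
              p$temporal_span, p$window_span,
              paste(utils::head(p$median_days, 6), collapse = ", ")))
  invisible(x)
}

#' Planned median-day sequence
#'
#' Enumerates window median days from the first median by a fixed interval up
#' to the last median, appending a clamped final value when the ladder
#' overshoots. With first median 46, interval 14 and last median 1810 this
#' gives 127 windows.
#'
#' @param first_median,interval,last_median integers, days.
#' @export
median_day_sequence <- function(first_median, interval, last_median) {
  stopifnot(interval >= 1, last_median >= first_median)
  s <- seq(first_median, last_median, by = interval)
  if (s[length(s)] != last_median) s <- c(s, last_median)
  as.integer(s)
}
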