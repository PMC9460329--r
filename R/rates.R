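#' Rate series container
#'
#' Timestamped heart-rate (beats/min) or respiratory-rate (breaths/min)
#' estimates.
#'
#' @param times Seconds, strictly increasing.
#' @param rates Beats/min or breaths/min; `NA` marks absent output (e.g.
#'   warm-up).
#' @param kind `"HR"` or `"RR"`.
#' @param smoothing Free-text description of any smoothing applied.
#' @return A data frame of class `rate_series` with columns `time_s` and
#'   `rate`, plus `kind`/`smoothing` attributes.
#' @export
rate_series <- function(times, rates, kind = c("HR", "RR"),
                        smoothing = "none") {
  kind <- match.arg(kind)
  if (length(times) != length(rates)) {
    stop("rate_series: 'times' and 'rates' lengths differ")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("rate_series: 'times' must be strictly increasing")
  }
  if (any(rates[!is.na(rates)] <= 0)) {
    stop("rate_series: rates must be positive")
  }
  out <- data.frame(time_s = as.numeric(times), rate = as.numeric(rates))
  attr(out, "kind") <- kind
  attr(out, "smoothing") <- smoothing
  class(out) <- c("rate_series", "data.frame")
  out
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %s, %d values (%s smoothing)\n",
              attr(x, "kind"), nrow(x), attr(x, "smoothing")))
  ok <- !is.na(x$rate)
  if (any(ok)) {
    cat(sprintf("  mean %.2f, range [%.2f, %.2f]\n", mean(x$rate[ok]),
                min(x$rate[ok]), max(x$rate[ok])))
  }
  invisible(x)
}

# Trailing (causal) moving mean. partial = TRUE averages whatever history
# is available before the window fills; otherwise the warm-up is NA.
trailing_mean <- function(x, k, partial = FALSE) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  cs <- cumsum(x)
  out <- rep(NA_real_, n)
  full <- seq_len(n) >= k
  if (any(full)) {
    i <- which(full)
    out[i] <- (cs[i] - c(0, cs)[i - k + 1]) / k
  }
  if (partial) {
    i <- which(!full)
    out[i] <- cs[i] / i
  }
  out
}

#' Breath-to-breath respiratory rate
#'
#' Computed directly from respiratory event timing after false-positive
#' reduction: for each consecutive pair of breaths, the rate is
#' `60 / (t2 - t1)` breaths/min, stamped at `t2`. Each breath's time is
#' taken at the event's positive edge (`t - h/N`), which is the
#' respiratory peak: the comparator run starts where the crest turns into
#' the expiratory fall, so the positive edge is the stable peak-to-peak
#' anchor (the event-end timestamp sits at the trough and can retreat by a
#' fraction of a beat when a late pulse splits the breath). Set
#' `anchor = "end"` to use the raw event timestamps instead.
#'
#' @param resp_events An [event_stream()] of respiratory events (or a
#'   `classified_events` object, in which case its `respiratory` element is
#'   used).
#' @param anchor `"peak"` (positive edge, default) or `"end"` (event
#'   timestamp).
#' @return A [rate_series()] of kind `"RR"` (empty for < 2 events).
#' @export
breath_to_breath_rr <- function(resp_events, anchor = c("peak", "end")) {
  anchor <- match.arg(anchor)
  if (inherits(resp_events, "classified_events")) {
    resp_events <- resp_events$respiratory
  }
  stopifnot(inherits(resp_events, "event_stream"))
  N <- stream_rate(resp_events)
  t <- if (anchor == "peak") resp_events$t - resp_events$h / N
       else resp_events$t
  if (length(t) < 2) {
    return(rate_series(numeric(), numeric(), kind = "RR"))
  }
  rate_series(t[-1], 60 / diff(t), kind = "RR")
}

#' Event-to-event smoothed heart rate
#'
#' At each cardiac event the instantaneous rate is `60 / period`; the
#' estimate is the mean of the last 30 instantaneous rates, smoothed by a
#' causal six-sample moving average (partial averages are used while the
#' smoother's own window fills, so the first post-warm-up estimates are
#' defined). Output is absent until 30 periods have accumulated.
#'
#' @param ps A [period_series()], or a list with `periods` and `times`
#'   such as the output of [median_compensate()].
#' @param window Number of instantaneous rates in the running mean.
#' @param smooth_k Length of the final moving-average smoother.
#' @return A [rate_series()] of kind `"HR"`.
#' @export
event_hr <- function(ps, window = 30, smooth_k = 6) {
  times <- ps$times
  periods <- ps$periods
  if (is.null(times)) times <- seq_along(periods)
  keep <- !is.na(periods)
  times <- times[keep]
  periods <- periods[keep]
  inst <- 60 / periods
  win <- trailing_mean(inst, window)
  sm <- rep(NA_real_, length(win))
  ok <- which(!is.na(win))
  if (length(ok) > 0) {
    sm[ok] <- trailing_mean(win[ok], smooth_k, partial = TRUE)
  }
  rate_series(times, sm, kind = "HR",
              smoothing = sprintf("%d-event mean + %d-sample average",
                                  window, smooth_k))
}

#' Windowed heart rate
#'
#' Nonoverlapping windows aligned to t = 0 of the record; within each
#' window the rate is `60 / mean(periods)`. Empty windows are absent from
#' the output.
#'
#' @param ps A [period_series()].
#' @param window_s Window length in seconds (15, 30 or 60 in typical use).
#' @return A [rate_series()] of kind `"HR"`, stamped at window starts.
#' @export
windowed_hr <- function(ps, window_s = 60) {
  stopifnot(inherits(ps, "period_series"))
  if (length(ps$periods) == 0) {
    return(rate_series(numeric(), numeric(), kind = "HR"))
  }
  win <- floor(ps$times / window_s)
  starts <- sort(unique(win))
  hr <- vapply(starts, function(w) 60 / mean(ps$periods[win == w]),
               numeric(1))
  rate_series(starts * window_s, hr, kind = "HR",
              smoothing = sprintf("%gs window mean", window_s))
}

#' Ground-truth heart rate from annotated beat times
#'
#' The reference construction mirrors the estimator: beat-to-beat
#' instantaneous rate, then the mean over the past 30 beats. No further
#' smoothing is applied by default.
#'
#' @param beat_times Ascending beat times in seconds.
#' @param window Number of beat-to-beat rates in the running mean.
#' @param smooth_k Optional final moving-average length (0 disables, the
#'   default).
#' @return A [rate_series()] of kind `"HR"`.
#' @export
ground_truth_hr <- function(beat_times, window = 30, smooth_k = 0) {
  if (length(beat_times) < 2) {
    return(rate_series(numeric(), numeric(), kind = "HR"))
  }
  inst <- 60 / diff(beat_times)
  win <- trailing_mean(inst, window)
  if (smooth_k > 1) {
    ok <- which(!is.na(win))
    win[ok] <- trailing_mean(win[ok], smooth_k, partial = TRUE)
  }
  rate_series(beat_times[-1], win, kind = "HR",
              smoothing = sprintf("%d-beat mean", window))
}
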