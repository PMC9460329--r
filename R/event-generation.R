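#' Delayed comparator over a sample series
#'
#' Compares the band signal with a delayed copy of itself: the binary event
#' signal is `V(n) = 1` when `Y(n + p) < Y(n)` (the signal is falling over
#' the delay window) and 0 otherwise, including ties. The cumulative sum
#' `C(n)` counts consecutive high samples and resets to zero at each
#' falling edge of `V`; the final count before a reset is the event period
#' `H`. The default delay of 10 samples (50 ms at 200 Hz) balances noise
#' immunity against sensitivity to the brief cardiac pulse; `p` is not
#' rescaled with the sampling rate.
#'
#' @param series A [sample_series()].
#' @param p Delay in samples (>= 1).
#' @return An object of class `comparator_trace`: list with the delay `p`,
#'   binary vector `v` and cumulative count `c`, both of the same length as
#'   the input (the last `p` samples carry `v = 0`).
#' @export
#' @examples
#' s <- sample_series(c(5, 4, 3, 2, 1, 2, 3, 4, 5), 200)
#' comparator(s, p = 2)$v
comparator <- function(series, p = 10) {
  stopifnot(inherits(series, "sample_series"))
  p <- as.integer(p)
  if (p < 1L) stop("comparator: 'p' must be >= 1")
  y <- series$values
  L <- length(y)
  if (L < p + 2L) stop("comparator: series shorter than p + 2 samples")
  v <- integer(L)
  v[seq_len(L - p)] <- as.integer(y[(1L + p):L] < y[seq_len(L - p)])
  # run-length cumulative count, reset where v == 0
  cc <- integer(L)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 1L) {
      cc[starts[k]:ends[k]] <- seq_len(r$lengths[k])
    }
  }
  structure(list(p = p, v = v, c = cc), class = "comparator_trace")
}

#' Integrate a comparator trace into an event stream
#'
#' Each maximal run of `V = 1` that terminates in a falling edge within the
#' record becomes one event: `h` is the run length; the timestamp `t` is
#' the time of the falling-edge sample (the first `V = 0` sample after the
#' run, so that `t - h/N` is the time of the run's first sample); `v1` is
#' the amplitude at the positive edge (first sample of the run) and `v2`
#' the amplitude at the negative edge. A run still open at the end of the
#' record is discarded.
#'
#' @param trace A [comparator()] trace.
#' @param series The [sample_series()] the trace was computed from.
#' @return An [event_stream()].
#' @export
integrate_to_events <- function(trace, series) {
  stopifnot(inherits(trace, "comparator_trace"),
            inherits(series, "sample_series"))
  y <- series$values
  L <- length(y)
  if (length(trace$v) != L) {
    stop("integrate_to_events: trace and series lengths differ")
  }
  N <- series$sample_rate_hz
  r <- rle(trace$v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run must be closed by a genuine falling edge: the comparator is
  # undefined for the last p samples, so a run touching that boundary is
  # still open at end-of-record and is discarded
  keep <- r$values == 1L & ends < (L - trace$p)
  s <- starts[keep]
  h <- r$lengths[keep]
  e <- ends[keep] + 1L                 # falling-edge sample (first v = 0)
  event_stream(
    t = series$start_time_s + (e - 1L) / N,
    h = h,
    v1 = y[s],
    v2 = y[e],
    sample_rate_hz = N
  )
}

#' Generate events from a sample series
#'
#' Convenience wrapper running [comparator()] then [integrate_to_events()].
#'
#' @inheritParams comparator
#' @return An [event_stream()].
#' @export
generate_events <- function(series, p = 10) {
  integrate_to_events(comparator(series, p), series)
}
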