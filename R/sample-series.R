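#' Uniformly sampled band waveform
#'
#' A `sample_series` holds a single channel of amplitudes (mV) sampled at a
#' fixed rate. Sample `n` (0-based) corresponds to time
#' `start_time_s + n / sample_rate_hz`.
#'
#' @param values Numeric vector of amplitudes in mV. Must be finite.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample in seconds.
#'
#' @return An object of class `sample_series`: a list with elements
#'   `values`, `sample_rate_hz` and `start_time_s`.
#' @export
#' @examples
#' s <- sample_series(sin(2 * pi * 1 * seq(0, 2, by = 1 / 200)), 200)
#' length(series_times(s))
sample_series <- function(values, sample_rate_hz, start_time_s = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("sample_series: 'values' must not be empty")
  }
  if (!all(is.finite(values))) {
    stop("sample_series: 'values' must be finite")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_series: 'sample_rate_hz' must be a single positive number")
  }
  structure(
    list(values = values,
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "sample_series"
  )
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              length(x$values), x$sample_rate_hz, x$start_time_s,
              x$start_time_s + (length(x$values) - 1) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.sample_series <- function(x) length(x$values)

#' Sample times of a series
#'
#' @param series A [sample_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "sample_series"))
  series$start_time_s +
    (seq_along(series$values) - 1) / series$sample_rate_hz
}

#' @export
as.data.frame.sample_series <- function(x, ...) {
  data.frame(time_s = series_times(x), amplitude_mv = x$values)
}

#' Read/write a sample series as CSV
#'
#' CSV dialect: header line `time_s,amplitude_mv`, comma separator, `.`
#' decimal. The sample rate is inferred on read from the median time step
#' unless given explicitly.
#'
#' @param series A [sample_series()].
#' @param path File path.
#' @param sample_rate_hz Optional explicit sample rate for reading; when
#'   `NULL` the rate is inferred from the time column.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a [sample_series()].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "sample_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, sample_rate_hz = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mv") %in% names(d))) {
    stop("read_series_csv: expected columns 'time_s' and 'amplitude_mv'")
  }
  if (is.null(sample_rate_hz)) {
    if (nrow(d) < 2L) stop("read_series_csv: cannot infer rate from < 2 rows")
    sample_rate_hz <- 1 / stats::median(diff(d$time_s))
  }
  sample_series(d$amplitude_mv, sample_rate_hz, start_time_s = d$time_s[1])
}

#' Anti-alias filter and resample a raw recording
#'
#' Applies a low-pass Butterworth filter followed by resampling onto a
#' uniform grid at `target_rate_hz`. The defaults (second-order filter,
#' 100 Hz cut-off, 200 Hz target) match the acquisition chain used for
#' high-rate bench recordings of the band signal. Filtering is zero-phase
#' (forward-backward) by default, appropriate for offline processing; set
#' `causal = TRUE` for a single causal pass emulating streaming use.
#'
#' @param raw A [sample_series()] at the original (high) rate.
#' @param cutoff_hz Low-pass cut-off frequency in Hz; must be below the
#'   Nyquist frequency of `raw`.
#' @param order Butterworth filter order.
#' @param target_rate_hz Output sampling rate in Hz (<= input rate).
#' @param causal Use a single forward filter pass instead of zero-phase
#'   filtering.
#' @return A [sample_series()] at `target_rate_hz`.
#' @export
#' @examples
#' raw <- sample_series(rep(1, 1000), 2000)
#' out <- preprocess(raw, cutoff_hz = 100, target_rate_hz = 200)
#' range(out$values)  # DC gain 1
preprocess <- function(raw, cutoff_hz = 100, order = 2,
                       target_rate_hz = 200, causal = FALSE) {
  stopifnot(inherits(raw, "sample_series"))
  if (cutoff_hz >= raw$sample_rate_hz / 2) {
    stop("preprocess: 'cutoff_hz' must be below the Nyquist frequency")
  }
  if (target_rate_hz > raw$sample_rate_hz) {
    stop("preprocess: 'target_rate_hz' must not exceed the input rate")
  }
  bf <- signal::butter(order, cutoff_hz / (raw$sample_rate_hz / 2),
                       type = "low")
  y <- if (causal) {
    as.numeric(signal::filter(bf, raw$values))
  } else {
    # odd-reflection padding suppresses the forward-backward filter's
    # edge transients
    v <- raw$values
    L <- length(v)
    np <- min(L - 1L, 3L * ceiling(raw$sample_rate_hz / cutoff_hz))
    left <- 2 * v[1] - v[(np + 1L):2L]
    right <- 2 * v[L] - v[(L - 1L):(L - np)]
    yy <- as.numeric(signal::filtfilt(bf, c(left, v, right)))
    yy[(np + 1L):(np + L)]
  }
  t_in <- series_times(raw)
  t_end <- t_in[length(t_in)]
  t_out <- seq(raw$start_time_s, t_end, by = 1 / target_rate_hz)
  v_out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  sample_series(v_out, target_rate_hz, start_time_s = raw$start_time_s)
}
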