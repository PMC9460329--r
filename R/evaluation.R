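#' Match detected peaks to ground truth
#'
#' Greedy one-to-one nearest matching within a time tolerance: candidate
#' pairs are considered in order of increasing absolute time difference and
#' accepted while both members are unmatched. Matched detections are true
#' positives; unmatched detections false positives; unmatched truths false
#' negatives.
#'
#' @param detected_times,truth_times Sorted peak times in seconds.
#' @param tolerance_s Matching tolerance (one-sided) in seconds. Typical
#'   choices: 0.15 s for heartbeats, 0.5 s for breaths.
#' @return A list of class `detection_report` with counts `tp`, `fp`,
#'   `fn` and percentages `sensitivity`, `precision`, `miss_rate`,
#'   `false_discovery_rate`.
#' @export
#' @examples
#' match_events(c(1.05, 2.9), c(1, 2, 3), tolerance_s = 0.15)
match_events <- function(detected_times, truth_times, tolerance_s) {
  nd <- length(detected_times)
  nt <- length(truth_times)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    dmat <- abs(outer(detected_times, truth_times, "-"))
    cand <- which(dmat <= tolerance_s, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  structure(
    list(tp = tp, fp = fp, fn = fn,
         sensitivity = sens, precision = prec,
         miss_rate = 100 - sens, false_discovery_rate = 100 - prec),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> TP %d  FP %d  FN %d\n  sensitivity %.2f%%  precision %.2f%%  miss %.2f%%  FDR %.2f%%\n",
    x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$miss_rate,
    x$false_discovery_rate))
  invisible(x)
}

#' Rate-estimate error statistics
#'
#' The estimate is resampled onto the truth timestamps by previous-value
#' hold (truth times preceding the first estimate are dropped), then the
#' absolute error statistics are computed.
#'
#' @param estimate,truth [rate_series()] objects of the same kind.
#' @return A list with `mae`, `sd`, `median_ae` (all in beats or breaths
#'   per minute) and `n` (compared points).
#' @export
rate_error <- function(estimate, truth) {
  stopifnot(inherits(estimate, "rate_series"),
            inherits(truth, "rate_series"))
  e <- estimate[!is.na(estimate$rate), , drop = FALSE]
  g <- truth[!is.na(truth$rate), , drop = FALSE]
  if (nrow(e) == 0 || nrow(g) == 0) {
    return(list(mae = NA_real_, sd = NA_real_, median_ae = NA_real_, n = 0L))
  }
  held <- stats::approx(e$time_s, e$rate, xout = g$time_s,
                        method = "constant", f = 0, rule = c(1, 2))$y
  ok <- !is.na(held)
  ae <- abs(held[ok] - g$rate[ok])
  list(mae = mean(ae), sd = stats::sd(ae),
       median_ae = stats::median(ae), n = length(ae))
}

# Round half up to `digits` decimals (the convention used for the
# kilobyte figures in the size tables).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Storage size of a conventional raw recording
#'
#' Models the conventional acquisition pipeline where every sample is
#' stored with a timestamp: `bytes = duration * rate * (sample_bits +
#' timestamp_bits) / 8`. An 8-hour single-channel recording at 200 Hz with
#' 24-bit samples and 32-bit timestamps comes to 38.45 MB. Binary
#' (1024-based) divisors are used for kB/MB throughout.
#'
#' @param duration_s Recording length in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param sample_bits,timestamp_bits Record field widths in bits
#'   (multiples of 8).
#' @return A list with `samples`, `bytes` and `mb`.
#' @export
#' @examples
#' recording_size(8 * 3600, 200)$mb  # 38.45
recording_size <- function(duration_s, rate_hz,
                           sample_bits = 24, timestamp_bits = 32) {
  if (sample_bits %% 8 != 0 || timestamp_bits %% 8 != 0) {
    stop("recording_size: bit widths must be multiples of 8")
  }
  samples <- duration_s * rate_hz
  bytes <- samples * (sample_bits + timestamp_bits) / 8
  list(samples = samples, bytes = bytes, mb = bytes / 1024^2)
}

#' Data sizes of the raw, event and result streams
#'
#' Compares the three storage strategies for one recording: raw samples
#' (8 bytes each: 4-byte timestamp + 4-byte value), full events (16 bytes
#' each) and result records after on-device rate estimation (8 bytes each,
#' the edge amplitudes discarded). Kilobyte figures use 1024-byte
#' kilobytes, rounded half-up to 2 decimals.
#'
#' @param n_samples Number of raw samples.
#' @param n_events Number of events.
#' @param raw_record_bytes,event_record_bytes,result_record_bytes Record
#'   sizes in bytes.
#' @return A list with byte and kB figures for `raw`, `events` and
#'   `results`, plus the raw/event `reduction_factor`.
#' @export
#' @examples
#' stream_sizes(143832, 1045)
stream_sizes <- function(n_samples, n_events,
                         raw_record_bytes = 8,
                         event_record_bytes = 16,
                         result_record_bytes = 8) {
  if (n_samples < 0 || n_events < 0) {
    stop("stream_sizes: counts must be non-negative")
  }
  raw <- n_samples * raw_record_bytes
  ev <- n_events * event_record_bytes
  res <- n_events * result_record_bytes
  list(raw_bytes = raw, event_bytes = ev, result_bytes = res,
       raw_kb = round_half_up(raw / 1024),
       event_kb = round_half_up(ev / 1024),
       result_kb = round_half_up(res / 1024),
       reduction_factor = if (ev > 0) raw / ev else NA_real_)
}

#' Bus transfer time
#'
#' Pure transfer-time model for reading an ADC word over a serial bus:
#' `bits / clock_hz`, reported in microseconds (no protocol overhead).
#' Reading a 24-bit word over a 6 MHz SPI bus takes 4 us.
#'
#' @param bits Word size in bits.
#' @param clock_hz Bus clock in Hz.
#' @return Transfer time in microseconds.
#' @export
#' @examples
#' bus_read_time(24, 6e6)  # 4
bus_read_time <- function(bits, clock_hz) {
  if (clock_hz <= 0) stop("bus_read_time: 'clock_hz' must be positive")
  bits / clock_hz * 1e6
}
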