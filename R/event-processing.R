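#' Event-processing parameters
#'
#' @param h_split Event-period threshold (samples) separating respiratory
#'   (`h > h_split`) from cardiac (`h <= h_split`) events, and the maximum
#'   inter-event gap (in samples) below which two long events are treated
#'   as one breath split by a heartbeat. Defined at 200 Hz and not rescaled
#'   with the sampling rate.
#' @param min_resp_interval_s Minimum credible interval between breaths
#'   (s); the default 1.0 corresponds to a 60 breaths/min ceiling.
#' @param min_card_interval_s Minimum credible interval between heartbeats
#'   (s); the default 1/3 corresponds to a 180 beats/min ceiling.
#' @return A list of class `processing_params`.
#' @export
processing_params <- function(h_split = 20,
                              min_resp_interval_s = 1.0,
                              min_card_interval_s = 1 / 3) {
  if (h_split <= 0 || min_resp_interval_s <= 0 || min_card_interval_s <= 0) {
    stop("processing_params: all parameters must be positive")
  }
  structure(list(h_split = h_split,
                 min_resp_interval_s = min_resp_interval_s,
                 min_card_interval_s = min_card_interval_s),
            class = "processing_params")
}

#' Merge respiratory events split by a heartbeat
#'
#' A heartbeat falling on the falling flank of a breath briefly interrupts
#' the comparator run, presenting one breath as two long events separated
#' by a short gap. For each consecutive pair (E1, E2) with both event
#' periods above `h_split`, the inter-event period is
#' `P = t2 - h2/N - t1`. When `P * N < h_split` the pair is rewritten as a
#' short cardiac blip (period `round(P * N)`, at least 1, ending where E2
#' begins, amplitudes `v1 = E2$v1`, `v2 = E1$v2`) followed by the merged
#' respiratory event (period `h1 + h2`, timestamp `t2`, `v1 = E1$v1`,
#' `v2 = E2$v2`). The scan is left-to-right and a merged event may merge
#' again with its successor, so a breath split by several beats collapses
#' to a single respiratory event plus one blip per interruption. A
#' negative gap is treated as zero (adjacent events) and still merged.
#'
#' @param stream An [event_stream()].
#' @param params A [processing_params()].
#' @return An [event_stream()] with merged respiratory events and inserted
#'   cardiac blips, ordered by timestamp.
#' @export
merge_split_respiratory <- function(stream, params = processing_params()) {
  stopifnot(inherits(stream, "event_stream"))
  N <- stream_rate(stream)
  hs <- params$h_split
  n <- nrow(stream)
  if (n < 2) return(stream)
  out_t <- numeric(0); out_h <- numeric(0)
  out_v1 <- numeric(0); out_v2 <- numeric(0)
  emit <- function(t, h, v1, v2) {
    out_t <<- c(out_t, t); out_h <<- c(out_h, h)
    out_v1 <<- c(out_v1, v1); out_v2 <<- c(out_v2, v2)
  }
  cur <- as.list(stream[1, ])
  for (i in 2:n) {
    nxt <- as.list(stream[i, ])
    gap <- max(0, (nxt$t - nxt$h / N - cur$t)) * N
    if (cur$h > hs && nxt$h > hs && gap < hs) {
      # cardiac blip spanning the interruption
      emit(t = nxt$t - nxt$h / N, h = max(1, round(gap)),
           v1 = nxt$v1, v2 = cur$v2)
      cur <- list(t = nxt$t, h = cur$h + nxt$h, v1 = cur$v1, v2 = nxt$v2)
    } else {
      emit(cur$t, cur$h, cur$v1, cur$v2)
      cur <- nxt
    }
  }
  emit(cur$t, cur$h, cur$v1, cur$v2)
  event_stream(out_t, out_h, out_v1, out_v2, sample_rate_hz = N)
}

#' Classify events as respiratory or cardiac
#'
#' Thresholds the event period: events with `h > h_split` are respiratory,
#' the rest cardiac. Apply [merge_split_respiratory()] first so that
#' breaths split by a heartbeat are not double-counted.
#'
#' @inheritParams merge_split_respiratory
#' @return A list of class `classified_events` with [event_stream()]
#'   elements `respiratory` and `cardiac`.
#' @export
classify_events <- function(stream, params = processing_params()) {
  stopifnot(inherits(stream, "event_stream"))
  N <- stream_rate(stream)
  resp <- stream$h > params$h_split
  structure(
    list(respiratory = as_event_stream(stream[resp, , drop = FALSE], N),
         cardiac = as_event_stream(stream[!resp, , drop = FALSE], N),
         sample_rate_hz = N),
    class = "classified_events"
  )
}

#' @export
print.classified_events <- function(x, ...) {
  cat(sprintf("<classified_events> %d respiratory, %d cardiac @ %g Hz\n",
              nrow(x$respiratory), nrow(x$cardiac), x$sample_rate_hz))
  invisible(x)
}

# One left-to-right rejection sweep pass over a single class.
reject_sweep <- function(d, min_interval_s) {
  repeat {
    if (nrow(d) < 2) return(d)
    gaps <- diff(d$t)
    j <- which(gaps < min_interval_s)
    if (length(j) == 0) return(d)
    j <- j[1]
    # drop the event with the smaller period; ties drop the later one
    drop <- if (d$h[j] < d$h[j + 1]) j else j + 1L
    d <- d[-drop, , drop = FALSE]
  }
}

#' Reject physiologically impossible detections
#'
#' Within each class independently, whenever two consecutive surviving
#' events are closer in time than the class's minimum credible interval
#' (1 s for breaths, 1/3 s for beats at the defaults, i.e. 60 breaths/min
#' and 180 beats/min ceilings), the event with the smaller period `h` is
#' dropped (ties drop the later event). The sweep repeats left-to-right
#' until no violation remains; the operation is idempotent.
#'
#' @param ce A [classify_events()] result.
#' @param params A [processing_params()].
#' @return A `classified_events` object with offending events removed.
#' @export
reject_false_positives <- function(ce, params = processing_params()) {
  stopifnot(inherits(ce, "classified_events"))
  N <- ce$sample_rate_hz
  structure(
    list(respiratory = as_event_stream(
           reject_sweep(ce$respiratory, params$min_resp_interval_s), N),
         cardiac = as_event_stream(
           reject_sweep(ce$cardiac, params$min_card_interval_s), N),
         sample_rate_hz = N),
    class = "classified_events"
  )
}

#' Consolidate event chains into one event per breath
#'
#' A breath's falling flank reaches the event stream as a chain of events
#' separated by sub-threshold gaps: long respiratory pieces interleaved
#' with the short cardiac notches and interruptions left by the
#' heartbeats riding on the flank. [merge_split_respiratory()] joins
#' adjacent long pieces but a chain is still broken wherever a pulse
#' carves out its own short event. This operation finds maximal chains of
#' events whose inter-event gap is below `h_split` samples, keeps chains
#' containing at least one respiratory-scale event (total span above
#' `h_split`), and condenses each to a single event spanning the whole
#' chain: timestamp at the chain end, period equal to the full span in
#' samples, `v1` from the first and `v2` from the last event. The
#' positive edge of a consolidated event is therefore the true breath
#' peak (the onset of the expiratory fall), which is the stable anchor
#' for breath-to-breath timing. The usual inter-breath minimum-interval
#' rejection is applied to the result.
#'
#' @param stream An [event_stream()] (raw or merged).
#' @param params A [processing_params()].
#' @return An [event_stream()] with one event per detected breath.
#' @export
consolidate_breaths <- function(stream, params = processing_params()) {
  stopifnot(inherits(stream, "event_stream"))
  N <- stream_rate(stream)
  n <- nrow(stream)
  if (n == 0) return(stream)
  starts <- stream$t - stream$h / N
  gap_n <- c(Inf, (starts[-1] - stream$t[-n]) * N)
  chain_id <- cumsum(gap_n >= params$h_split)
  pieces <- split(seq_len(n), chain_id)
  out <- lapply(pieces, function(idx) {
    first <- idx[1]; last <- idx[length(idx)]
    span <- round((stream$t[last] - starts[first]) * N)
    list(t = stream$t[last], h = span,
         v1 = stream$v1[first], v2 = stream$v2[last])
  })
  d <- do.call(rbind, lapply(out, as.data.frame))
  d <- d[d$h > params$h_split, , drop = FALSE]
  d <- reject_sweep(d, params$min_resp_interval_s)
  event_stream(d$t, d$h, d$v1, d$v2, sample_rate_hz = N)
}

#' Full event-processing chain
#'
#' Runs [merge_split_respiratory()], [classify_events()] and
#' [reject_false_positives()] in order.
#'
#' @inheritParams merge_split_respiratory
#' @return A `classified_events` object.
#' @export
process_events <- function(stream, params = processing_params()) {
  reject_false_positives(
    classify_events(merge_split_respiratory(stream, params), params),
    params)
}
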