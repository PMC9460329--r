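#' Event stream container
#'
#' An event is a maximal falling segment of the band signal detected by the
#' delayed comparator, encoded by four fields: `t` (timestamp at the event
#' end, seconds), `h` (event period: number of samples the comparator output
#' stayed high), and the sensor amplitudes at the positive (`v1`) and
#' negative (`v2`) edges in mV. On disk each event occupies exactly 16
#' bytes (see [write_events()]).
#'
#' @param t Numeric vector of event-end timestamps in seconds, strictly
#'   increasing.
#' @param h Integer vector of event periods in samples (>= 1).
#' @param v1,v2 Numeric amplitudes (mV) at the positive/negative edge.
#' @param sample_rate_hz Sampling rate (Hz) of the series that produced the
#'   events.
#'
#' @return A data frame of class `event_stream` with columns `t`, `h`,
#'   `v1`, `v2` and attribute `sample_rate_hz`.
#' @export
event_stream <- function(t = numeric(), h = integer(),
                         v1 = numeric(), v2 = numeric(),
                         sample_rate_hz) {
  if (missing(sample_rate_hz)) stop("event_stream: 'sample_rate_hz' required")
  n <- length(t)
  if (length(h) != n || length(v1) != n || length(v2) != n) {
    stop("event_stream: field lengths differ")
  }
  if (n > 0) {
    if (any(h < 1)) stop("event_stream: 'h' must be >= 1")
    if (any(diff(t) <= 0)) stop("event_stream: 't' must be strictly increasing")
  }
  out <- data.frame(t = as.numeric(t), h = as.numeric(h),
                    v1 = as.numeric(v1), v2 = as.numeric(v2))
  attr(out, "sample_rate_hz") <- as.numeric(sample_rate_hz)
  class(out) <- c("event_stream", "data.frame")
  out
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events @ %g Hz\n",
              nrow(x), attr(x, "sample_rate_hz")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Sampling rate of an event stream
#' @param stream An [event_stream()].
#' @return Sampling rate in Hz.
#' @export
stream_rate <- function(stream) attr(stream, "sample_rate_hz")

# Internal: rebuild stream from a plain data frame, keeping the rate.
as_event_stream <- function(d, sample_rate_hz) {
  event_stream(d$t, d$h, d$v1, d$v2, sample_rate_hz = sample_rate_hz)
}

#' Binary event-file I/O
#'
#' Events are serialized as consecutive 16-byte little-endian records: the
#' timestamp as a 4-byte unsigned integer sample index (`round(t * N)`),
#' the event period as a 4-byte unsigned integer, and the two edge
#' amplitudes as 4-byte IEEE-754 floats. `write_events()` returns the byte
#' count written (`16 * n_events`); `read_events()` is its inverse up to
#' single-precision rounding of the amplitudes.
#'
#' @param stream An [event_stream()].
#' @param path File path (conventionally `.evt`).
#' @param sample_rate_hz Sampling rate used to map stored sample indices
#'   back to seconds on read.
#' @return `write_events` returns the number of bytes written;
#'   `read_events` returns an [event_stream()].
#' @export
#' @examples
#' s <- event_stream(t = c(1, 2), h = c(5, 40), v1 = c(10, 20),
#'                   v2 = c(0, 5), sample_rate_hz = 200)
#' f <- tempfile(fileext = ".evt")
#' write_events(s, f)  # 32 bytes
#' read_events(f, 200)
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  n <- nrow(stream)
  rate <- stream_rate(stream)
  con <- file(path, "wb")
  on.exit(close(con))
  if (n > 0) {
    t_idx <- as.integer(round(stream$t * rate))
    if (any(t_idx < 0)) stop("write_events: negative sample index")
    h_int <- as.integer(round(stream$h))
    for (i in seq_len(n)) {
      writeBin(t_idx[i], con, size = 4L, endian = "little")
      writeBin(h_int[i], con, size = 4L, endian = "little")
      writeBin(stream$v1[i], con, size = 4L, endian = "little")
      writeBin(stream$v2[i], con, size = 4L, endian = "little")
    }
  }
  16L * n
}

#' @rdname write_events
#' @export
read_events <- function(path, sample_rate_hz) {
  nbytes <- file.size(path)
  if (is.na(nbytes)) stop("read_events: file not found: ", path)
  if (nbytes %% 16 != 0) {
    stop("read_events: truncated event file (length not a multiple of 16)")
  }
  n <- nbytes %/% 16
  if (n == 0) {
    return(event_stream(sample_rate_hz = sample_rate_hz))
  }
  raw <- readBin(path, "raw", n = nbytes)
  field_bytes <- function(k) {
    # bytes of 4-byte field k (0-based) in every 16-byte record
    idx <- rep((seq_len(n) - 1L) * 16L + k * 4L, each = 4L) + 1:4
    raw[idx]
  }
  t_idx <- readBin(field_bytes(0L), "integer", n = n, size = 4L,
                   endian = "little")
  h <- readBin(field_bytes(1L), "integer", n = n, size = 4L,
               endian = "little")
  v1 <- readBin(field_bytes(2L), "numeric", n = n, size = 4L,
                endian = "little")
  v2 <- readBin(field_bytes(3L), "numeric", n = n, size = 4L,
                endian = "little")
  if (any(diff(t_idx) <= 0)) {
    stop("read_events: timestamps not strictly increasing")
  }
  event_stream(t = t_idx / sample_rate_hz, h = h, v1 = v1, v2 = v2,
               sample_rate_hz = sample_rate_hz)
}
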