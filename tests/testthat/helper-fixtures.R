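# Shared fixture builders. All fixtures are generated in code; amplitudes
# used in binary round-trip tests are float32-representable (multiples of
# 0.25) so on-disk identity is exact.

make_stream <- function(t, h, v1 = NULL, v2 = NULL, rate = 200) {
  n <- length(t)
  if (is.null(v1)) v1 <- seq(100, by = 0.25, length.out = n)
  if (is.null(v2)) v2 <- seq(50, by = 0.25, length.out = n)
  event_stream(t = t, h = h, v1 = v1, v2 = v2, sample_rate_hz = rate)
}

random_stream <- function(n, rate = 200) {
  # consecutive comparator runs are always separated by at least one
  # zero sample, so successive events never touch
  gaps <- sample(2:150, n, replace = TRUE)
  t_idx <- cumsum(gaps)
  h <- pmin(sample.int(50, n, replace = TRUE), gaps - 1L)
  make_stream(t_idx / rate, h,
              v1 = sample(seq(0, 4000, by = 0.25), n),
              v2 = sample(seq(0, 4000, by = 0.25), n),
              rate = rate)
}

# Independent brute-force comparator: direct pairwise comparison.
brute_comparator_v <- function(y, p) {
  L <- length(y)
  v <- integer(L)
  for (n in seq_len(L - p)) v[n] <- as.integer(y[n + p] < y[n])
  v
}

# Independent run-length event scanner over a binary vector. The
# comparator output is only defined for the first length(v) - p samples;
# a run reaching that boundary is open at end-of-record, not an event.
brute_events <- function(v, y, rate, p) {
  out <- NULL
  n <- 1L
  limit <- length(v) - p
  while (n <= limit) {
    if (v[n] == 1L) {
      s <- n
      while (n <= limit && v[n] == 1L) n <- n + 1L
      if (n <= limit) {                   # run closed by a falling edge
        out <- rbind(out, data.frame(t = (n - 1) / rate, h = n - s,
                                     v1 = y[s], v2 = y[n]))
      }
    } else n <- n + 1L
  }
  out
}

# From-scratch bucket histogram of the last `cap` periods.
brute_bucket_counts <- function(periods, thresholds, cap = 30) {
  recent <- utils::tail(periods, cap)
  idx <- bucket_index(recent, thresholds)
  counts <- tabulate(idx, nbins = length(thresholds))
  means <- vapply(seq_along(thresholds), function(i) {
    x <- recent[idx == i]
    if (length(x) == 0) 0 else mean(x)
  }, numeric(1))
  list(counts = counts, means = means)
}

# Exhaustive majority search: all singles, then adjacent pairs, triples.
brute_majority <- function(counts, means) {
  nb <- length(counts)
  scan <- function(width, min_count) {
    best <- NULL
    for (j in seq_len(nb - width + 1)) {
      w <- j:(j + width - 1)
      s <- sum(counts[w])
      if (s > min_count && (is.null(best) || s > best$s)) {
        idx <- w[which.max(counts[w])]
        best <- list(s = s, index = idx,
                     mean = sum(means[w] * counts[w]) / s)
      }
    }
    best
  }
  for (spec in list(c(1, 20), c(2, 15), c(3, 15))) {
    b <- scan(spec[1], spec[2])
    if (!is.null(b)) return(b)
  }
  NULL
}
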