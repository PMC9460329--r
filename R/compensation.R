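#' Cardiac period series from classified events
#'
#' Periods between consecutive cardiac event timestamps; each period is
#' stamped with the time of the event that closes it.
#'
#' @param cardiac An [event_stream()] of cardiac events (or a
#'   `classified_events` object, in which case its `cardiac` element is
#'   used).
#' @return A list of class `period_series` with numeric vectors `times`
#'   (s) and `periods` (s), where `length(periods) == length(times)`.
#' @export
period_series <- function(cardiac) {
  if (inherits(cardiac, "classified_events")) cardiac <- cardiac$cardiac
  stopifnot(inherits(cardiac, "event_stream"))
  t <- cardiac$t
  if (length(t) < 2) {
    return(structure(list(times = numeric(), periods = numeric()),
                     class = "period_series"))
  }
  structure(list(times = t[-1], periods = diff(t)),
            class = "period_series")
}

#' Moving median of a period series
#'
#' Trailing median over the previous `k` periods (excluding the current
#' one), the local statistic the missed-beat compensation keys on. The
#' 20-period variant reproduces the diagnostic view of cardiac periods
#' against integer multiples of the running median; compensation itself
#' uses 30.
#'
#' @param periods Numeric vector of cardiac periods (s).
#' @param k Window length in periods.
#' @return Numeric vector of the same length; `NA` until `k` prior periods
#'   exist.
#' @export
moving_median <- function(periods, k = 30) {
  n <- length(periods)
  out <- rep(NA_real_, n)
  if (n > k) {
    med <- zoo::rollapply(periods, width = k, FUN = stats::median,
                          align = "right", fill = NA)
    # med[i] covers periods (i-k+1):i; the "past k" for element i+1
    out[(k + 1):n] <- med[k:(n - 1)]
  }
  out
}

#' Median-harmonics compensation of missed beats
#'
#' For each cardiac period `h`, the running median `x` of the previous 30
#' periods defines candidate explanations `x, 2x, ..., 5x`: an overlong
#' period close to `k * x` is most likely `k - 1` missed beats. The period
#' is divided by the `k` minimising `|h - k * x|`, mapping it back onto
#' the prevailing beat-to-beat scale. For example, a beat-to-beat sequence
#' of 70, 32, 73 bpm is corrected to 70, 64, 64, 73 bpm: the 32 bpm
#' element is recognised as twice the prevailing period.
#'
#' Output is absent (`NA`) during the 30-period warm-up.
#'
#' @param periods A [period_series()] or numeric vector of periods (s).
#' @param window Number of prior periods in the running median.
#' @param max_harmonic Largest multiple of the median considered.
#' @return A list with `periods` (compensated periods, s), `k` (the chosen
#'   integer divisor) and `times` (if the input carried times).
#' @export
#' @examples
#' p <- c(rep(60 / 70, 30), 60 / 32)
#' median_compensate(p)$periods[31] # ~ 60/64
median_compensate <- function(periods, window = 30, max_harmonic = 5) {
  times <- NULL
  if (inherits(periods, "period_series")) {
    times <- periods$times
    periods <- periods$periods
  }
  n <- length(periods)
  med <- moving_median(periods, k = window)
  out <- rep(NA_real_, n)
  kk <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(med[i])) next
    cand <- seq_len(max_harmonic) * med[i]
    k <- which.min(abs(periods[i] - cand))
    out[i] <- periods[i] / k
    kk[i] <- k
  }
  list(periods = out, k = kk, times = times)
}

#' k-means compensation of missed beats over nonoverlapping windows
#'
#' Within each nonoverlapping window (aligned to t = 0), the cardiac
#' periods are clustered into three groups by k-means (Lloyd iterations)
#' seeded at the window median `x`, `2x` and `3x`. The most populated
#' cluster is taken as the true beat-to-beat period; the uncompensated
#' estimate is `60 / mean(dominant cluster)`. For compensation, each
#' element of the other clusters is scaled by the factor in
#' {1/2, 1/3, 1/4} bringing it closest to the dominant mean (an overlong
#' period spanning `k` beats is divided by `k`), and the heart rate is
#' recomputed over all adjusted periods.
#'
#' Windows with fewer than 3 periods yield `NA`. When the window is too
#' degenerate for k-means (fewer distinct values than centers), points are
#' assigned to the nearest seed directly, which is the fixed point of the
#' Lloyd iteration in that case.
#'
#' @param ps A [period_series()].
#' @param window_s Window length in seconds (15, 30 or 60 in typical use).
#' @return A data frame with one row per window: `window_start` (s), `n`
#'   (periods in window), `hr_comp` and `hr_uncomp` (beats/min).
#' @export
kmeans_compensate <- function(ps, window_s = 60) {
  stopifnot(inherits(ps, "period_series"))
  if (window_s <= 0) stop("kmeans_compensate: 'window_s' must be positive")
  if (length(ps$periods) == 0) {
    return(data.frame(window_start = numeric(), n = integer(),
                      hr_comp = numeric(), hr_uncomp = numeric()))
  }
  win <- floor(ps$times / window_s)
  starts <- sort(unique(win))
  res <- lapply(starts, function(w) {
    x <- ps$periods[win == w]
    if (length(x) < 3) {
      return(data.frame(window_start = w * window_s, n = length(x),
                        hr_comp = NA_real_, hr_uncomp = NA_real_))
    }
    m <- stats::median(x)
    seeds <- matrix(c(m, 2 * m, 3 * m))
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = seeds, iter.max = 100,
                      algorithm = "Lloyd")),
      error = function(e) NULL)
    cl <- if (is.null(km)) {
      # degenerate window: one Lloyd assignment step to the fixed seeds
      apply(abs(outer(x, as.numeric(seeds), "-")), 1, which.min)
    } else {
      km$cluster
    }
    sizes <- tabulate(cl, nbins = 3)
    dom <- which.max(sizes)
    dom_mean <- mean(x[cl == dom])
    adj <- x
    nd <- which(cl != dom)
    for (i in nd) {
      f <- 1 / (2:4)
      adj[i] <- x[i] * f[which.min(abs(x[i] * f - dom_mean))]
    }
    data.frame(window_start = w * window_s, n = length(x),
               hr_comp = 60 / mean(adj), hr_uncomp = 60 / dom_mean)
  })
  do.call(rbind, res)
}
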