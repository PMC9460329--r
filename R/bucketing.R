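#' Bucketing-algorithm state
#'
#' A nonuniform histogram of the last 30 cardiac periods over a fixed
#' threshold array, maintained incrementally so the algorithm runs with a
#' handful of floating-point operations per event. The state holds the
#' threshold array, a FIFO of the most recent periods, per-bucket running
#' means and element counters, and the last valid heart-rate output.
#'
#' @param thresholds Upper edges of the period buckets in seconds.
#' @param capacity FIFO length (number of recent periods retained).
#' @return An object of class `bucket_state`.
#' @export
bucket_state <- function(thresholds = c(0.4, 0.45, 0.5, 0.6, 0.7, 0.8,
                                        0.9, 1, 1.2, 1.6, 2, 2.4, 2.8, 3.2),
                         capacity = 30) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("bucket_state: 'thresholds' must be strictly increasing")
  }
  nb <- length(thresholds)
  structure(
    list(thresholds = thresholds,
         capacity = as.integer(capacity),
         fifo = numeric(0),
         means = numeric(nb),
         counts = integer(nb),
         last_valid_hr = NA_real_),
    class = "bucket_state"
  )
}

#' @export
print.bucket_state <- function(x, ...) {
  cat(sprintf("<bucket_state> %d/%d periods; last HR %s\n",
              length(x$fifo), x$capacity,
              if (is.na(x$last_valid_hr)) "none"
              else sprintf("%.1f bpm", x$last_valid_hr)))
  occ <- x$counts > 0
  if (any(occ)) {
    print(data.frame(bucket = which(occ),
                     upper_s = x$thresholds[occ],
                     count = x$counts[occ],
                     mean_s = round(x$means[occ], 4)))
  }
  invisible(x)
}

#' Bucket index for a cardiac period
#'
#' The 1-based position of the first threshold greater than or equal to
#' the period; e.g. a 0.67 s period falls in bucket 5 (the 0.7 s bucket)
#' under the default array. Periods beyond the last threshold clamp to
#' the last bucket.
#'
#' @param period Cardiac period in seconds (> 0); vectorised.
#' @param thresholds Bucket threshold array.
#' @return Integer bucket indices.
#' @export
#' @examples
#' bucket_index(0.67)  # 5
bucket_index <- function(period,
                         thresholds = bucket_state()$thresholds) {
  if (any(period <= 0)) stop("bucket_index: 'period' must be positive")
  idx <- findInterval(period, thresholds, left.open = TRUE) + 1L
  pmin(idx, length(thresholds))
}

#' Stream one period into the bucket state
#'
#' If the FIFO is full, the oldest period is evicted first: its bucket's
#' counter is decremented and the bucket mean downdated. The new period is
#' appended, its bucket counter incremented and the mean updated. The sum
#' of the counters always equals the FIFO length.
#'
#' @param state A [bucket_state()].
#' @param period New cardiac period in seconds (> 0).
#' @return The updated `bucket_state`.
#' @export
bucket_update <- function(state, period) {
  stopifnot(inherits(state, "bucket_state"))
  if (!is.finite(period) || period <= 0) {
    stop("bucket_update: 'period' must be a positive finite number")
  }
  if (length(state$fifo) >= state$capacity) {
    old <- state$fifo[1]
    state$fifo <- state$fifo[-1]
    i <- bucket_index(old, state$thresholds)
    n <- state$counts[i]
    state$means[i] <- if (n > 1) (state$means[i] * n - old) / (n - 1) else 0
    state$counts[i] <- n - 1L
  }
  i <- bucket_index(period, state$thresholds)
  n <- state$counts[i]
  state$means[i] <- (state$means[i] * n + period) / (n + 1)
  state$counts[i] <- n + 1L
  state$fifo <- c(state$fifo, period)
  state
}

#' Find the majority bucket group
#'
#' Checks three rules in decreasing priority: a single bucket holding more
#' than 20 of the 30 retained periods; two adjacent buckets jointly
#' holding more than 15; three adjacent buckets jointly holding more than
#' 15. When several windows qualify at the same priority, the one with the
#' largest count wins (ties: smallest index). For combined majorities the
#' returned mean is the count-weighted mean over the window and the
#' returned index is the window's most populated bucket.
#'
#' @param state A [bucket_state()].
#' @return `NULL` if no rule fires, else a list with `index`, `mean`
#'   (seconds), `window` (bucket indices) and `rule`
#'   (`"single"|"dual"|"triple"`).
#' @export
bucket_majority <- function(state) {
  stopifnot(inherits(state, "bucket_state"))
  cnt <- state$counts
  nb <- length(cnt)
  pick_window <- function(width, min_count) {
    if (nb < width) return(NULL)
    sums <- vapply(seq_len(nb - width + 1L),
                   function(j) sum(cnt[j:(j + width - 1L)]), numeric(1))
    ok <- which(sums > min_count)
    if (length(ok) == 0) return(NULL)
    j <- ok[which.max(sums[ok])]      # which.max takes the first on ties
    w <- j:(j + width - 1L)
    idx <- w[which.max(cnt[w])]
    list(index = idx,
         mean = sum(state$means[w] * cnt[w]) / sum(cnt[w]),
         window = w)
  }
  res <- pick_window(1L, 20L)
  if (!is.null(res)) return(c(res, rule = "single"))
  res <- pick_window(2L, 15L)
  if (!is.null(res)) return(c(res, rule = "dual"))
  res <- pick_window(3L, 15L)
  if (!is.null(res)) return(c(res, rule = "triple"))
  NULL
}

#' Heart rate from the bucket state
#'
#' When a majority group is found at index `i`, the base period is the
#' count-weighted mean over buckets `i - 1`, `i`, `i + 1`, capturing
#' heart-rate oscillation bucketed into neighbours. The algorithm then
#' scans buckets beyond `i + 1` holding more than three elements: if
#' dividing such a bucket's mean period by 2 or 3 yields a rate within
#' 20 beats/min of the established rate, those elements are missed-beat
#' multiples and are folded into the weighted mean at the divided period.
#' The output is `60 / final mean period`; with no majority the last valid
#' output is repeated (`NA` when none exists yet).
#'
#' @param state A [bucket_state()].
#' @return A list with `hr` (beats/min or `NA`) and the updated `state`
#'   (its `last_valid_hr` refreshed).
#' @export
bucket_hr <- function(state) {
  stopifnot(inherits(state, "bucket_state"))
  maj <- bucket_majority(state)
  if (is.null(maj)) {
    return(list(hr = state$last_valid_hr, state = state))
  }
  nb <- length(state$counts)
  i <- maj$index
  w <- max(1L, i - 1L):min(nb, i + 1L)
  cnt <- state$counts[w]
  tot_sum <- sum(state$means[w] * cnt)
  tot_n <- sum(cnt)
  est_hr <- 60 / (tot_sum / tot_n)
  if (i + 2L <= nb) {
    for (j in (i + 2L):nb) {
      if (state$counts[j] > 3L) {
        cand_per <- state$means[j] / c(2, 3)
        diffs <- abs(60 / cand_per - est_hr)
        ok <- which(diffs <= 20)
        if (length(ok) > 0) {
          d <- ok[which.min(diffs[ok])]
          tot_sum <- tot_sum + state$counts[j] * cand_per[d]
          tot_n <- tot_n + state$counts[j]
        }
      }
    }
  }
  hr <- 60 / (tot_sum / tot_n)
  state$last_valid_hr <- hr
  list(hr = hr, state = state)
}

#' Run the bucketing algorithm over a period series
#'
#' Streams each cardiac period through [bucket_update()] and records the
#' [bucket_hr()] output after every event.
#'
#' @param ps A [period_series()] or numeric vector of periods (s).
#' @param state Initial [bucket_state()].
#' @return A list with `times` (s, `NULL` for bare numeric input), `hr`
#'   (beats/min per event, `NA` before the first majority) and the final
#'   `state`.
#' @export
bucket_hr_stream <- function(ps, state = bucket_state()) {
  times <- NULL
  periods <- ps
  if (inherits(ps, "period_series")) {
    times <- ps$times
    periods <- ps$periods
  }
  hr <- rep(NA_real_, length(periods))
  for (i in seq_along(periods)) {
    state <- bucket_update(state, periods[i])
    res <- bucket_hr(state)
    hr[i] <- res$hr
    state <- res$state
  }
  list(times = times, hr = hr, state = state)
}
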