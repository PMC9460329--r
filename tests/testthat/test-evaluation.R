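test_that("event matching produces the documented counts and identities", {
  # identical lists: perfect scores
  r <- match_events(c(1, 2, 3), c(1, 2, 3), 0.1)
  expect_equal(r$fp, 0L); expect_equal(r$fn, 0L)
  expect_equal(r$sensitivity, 100); expect_equal(r$precision, 100)

  # truth {1,2,3}, detected {1.05, 2.9}, tol 0.15
  r <- match_events(c(1.05, 2.9), c(1, 2, 3), 0.15)
  expect_equal(r$tp, 2L); expect_equal(r$fp, 0L); expect_equal(r$fn, 1L)
  expect_equal(r$sensitivity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(r$precision, 100)

  # metric identities hold on random jittered subsets
  set.seed(29)
  for (i in 1:20) {
    truth <- sort(stats::runif(30, 0, 60))
    sub <- truth[stats::runif(30) < 0.8]
    det <- sort(sub + stats::rnorm(length(sub), 0, 0.05))
    r <- match_events(det, truth, 0.12)
    expect_equal(r$tp + r$fn, 30L)
    expect_equal(r$tp + r$fp, length(det))
    expect_equal(r$sensitivity, 100 * r$tp / (r$tp + r$fn))
    expect_equal(r$precision, 100 * r$tp / (r$tp + r$fp))
    expect_equal(r$miss_rate, 100 - r$sensitivity)
    expect_equal(r$false_discovery_rate, 100 - r$precision)
  }
})

test_that("greedy matching is one-to-one within tolerance", {
  # two detections near one truth: only one can match
  r <- match_events(c(0.95, 1.05), c(1), 0.15)
  expect_equal(r$tp, 1L); expect_equal(r$fp, 1L)
  # one detection between two truths matches the nearer
  r <- match_events(c(1.4), c(1, 1.5), 0.6)
  expect_equal(r$tp, 1L); expect_equal(r$fn, 1L)
})

test_that("rate-error statistics match direct recomputation", {
  a <- rate_series(1:10, rep(80, 10), kind = "HR")
  expect_equal(rate_error(a, a)$mae, 0)
  expect_equal(rate_error(a, a)$sd, 0)

  b <- rate_series(1:10, rep(81, 10), kind = "HR")
  e <- rate_error(b, a)
  expect_equal(e$mae, 1); expect_equal(e$sd, 0); expect_equal(e$median_ae, 1)

  set.seed(37)
  est <- rate_series(sort(stats::runif(40, 0, 100)),
                     stats::runif(40, 60, 100), kind = "HR")
  tru <- rate_series(sort(stats::runif(35, 0, 100)),
                     stats::runif(35, 60, 100), kind = "HR")
  e <- rate_error(est, tru)
  held <- stats::approx(est$time_s, est$rate, xout = tru$time_s,
                        method = "constant", f = 0, rule = c(1, 2))$y
  ae <- abs(held - tru$rate)[!is.na(held)]
  expect_equal(e$mae, mean(ae))
  expect_equal(e$median_ae, stats::median(ae))
})

test_that("recording size arithmetic reproduces the storage model", {
  r <- recording_size(8 * 3600, 200, 24, 32)
  expect_equal(r$bytes, 40320000)
  expect_equal(round(r$mb, 2), 38.45)
  expect_equal(recording_size(0, 200)$bytes, 0)
  expect_equal(recording_size(1, 1, 8, 0)$bytes, 1)
  expect_error(recording_size(10, 200, 12, 32), "multiples of 8")
})

test_that("stream sizes use 16-byte events, 8-byte records, binary kB", {
  s <- stream_sizes(143832, 1045)
  expect_equal(s$event_bytes, 16720)
  expect_equal(s$event_kb, 16.33)
  expect_equal(s$result_bytes, 8360)
  expect_equal(s$result_kb, 8.16)
  expect_equal(s$raw_kb, 1123.69)       # 143832 * 8 / 1024, half-up
  z <- stream_sizes(0, 0)
  expect_equal(z$event_bytes, 0)
  expect_true(is.na(z$reduction_factor))
})

test_that("bus read time is a pure transfer-time model", {
  expect_equal(bus_read_time(24, 6e6), 4)
  expect_equal(bus_read_time(24, 2e6), 12)
  expect_equal(bus_read_time(0, 1e6), 0)
  expect_error(bus_read_time(8, 0), "positive")
})

test_that("event encoding achieves the expected data-size reduction band", {
  out <- generate_band_signal(synthetic_config(duration_s = 300, seed = 41))
  ev <- generate_events(out$series, 10)
  sz <- stream_sizes(length(out$series), nrow(ev))
  expect_gte(sz$reduction_factor, 40)
  expect_lte(sz$reduction_factor, 140)
})
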