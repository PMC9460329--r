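test_that("breath-to-breath RR follows consecutive breath timing", {
  s <- make_stream(t = c(0.5, 3.5, 6.5, 9.5), h = rep(100, 4))
  rr <- breath_to_breath_rr(s)
  expect_equal(rr$rate, rep(20, 3))
  expect_equal(rr$time_s, c(3.5, 6.5, 9.5) - 0.5)  # peak anchor: t - h/N

  rr_end <- breath_to_breath_rr(s, anchor = "end")
  expect_equal(rr_end$rate, rep(20, 3))
  expect_equal(rr_end$time_s, c(3.5, 6.5, 9.5))

  two <- make_stream(t = c(1, 5), h = c(80, 80))
  expect_equal(breath_to_breath_rr(two)$rate, 15)
  one <- make_stream(t = 1, h = 80)
  expect_equal(nrow(breath_to_breath_rr(one)), 0L)
})

test_that("RR on noiseless periodic synthetic breathing is near-exact", {
  cfg <- synthetic_config(duration_s = 120, seed = 19, rr_sd = 0,
                          pulse_pp_mv = 0, noise_sd_mv = 0)
  out <- generate_band_signal(cfg)
  br <- consolidate_breaths(generate_events(out$series, 10))
  rr <- breath_to_breath_rr(br)
  truth <- rate_series(out$truth$breath_peak_times[-1],
                       60 / diff(out$truth$breath_peak_times), kind = "RR")
  err <- rate_error(rr, truth)
  expect_lt(err$mae, 0.05)
})

test_that("event HR averages the last 30 instantaneous rates", {
  # constant period
  ps <- list(times = cumsum(rep(0.7, 40)), periods = rep(0.7, 40))
  hr <- event_hr(ps)
  expect_true(all(is.na(hr$rate[1:29])))
  expect_equal(hr$rate[30:40], rep(60 / 0.7, 11), tolerance = 1e-9)

  # alternating 0.6/0.8: 30-event mean of {100, 75} = 87.5, smoothing
  # leaves the constant sequence unchanged
  ps <- list(times = cumsum(rep(c(0.6, 0.8), 25)),
             periods = rep(c(0.6, 0.8), 25))
  hr <- event_hr(ps)
  expect_equal(hr$rate[30:50], rep(87.5, 21), tolerance = 1e-9)

  # step change 60 -> 80 bpm transitions monotonically over ~30 events
  ps <- list(times = cumsum(c(rep(1, 40), rep(0.75, 40))),
             periods = c(rep(1, 40), rep(0.75, 40)))
  hr <- event_hr(ps)
  trans <- hr$rate[40:80]
  expect_true(all(diff(trans) >= -1e-9))
  expect_equal(hr$rate[80], 80, tolerance = 1e-6)
})

test_that("windowed HR equals brute-force per-window means", {
  ps <- structure(list(times = cumsum(rep(0.7, 300)),
                       periods = rep(0.7, 300)), class = "period_series")
  w <- windowed_hr(ps, 60)
  expect_true(all(abs(w$rate - 60 / 0.7) < 1e-9))

  one <- structure(list(times = 10, periods = 1.0), class = "period_series")
  expect_equal(windowed_hr(one, 15)$rate, 60)

  set.seed(23)
  per <- stats::runif(200, 0.5, 1.2)
  ps <- structure(list(times = cumsum(per), periods = per),
                  class = "period_series")
  for (win in c(15, 30, 60)) {
    w <- windowed_hr(ps, win)
    idx <- floor(ps$times / win)
    for (r in seq_len(nrow(w))) {
      sel <- idx == w$time_s[r] / win
      expect_equal(w$rate[r], 60 / mean(per[sel]), tolerance = 1e-9)
    }
  }
})

test_that("ground-truth HR mirrors the 30-beat rolling construction", {
  gt <- ground_truth_hr(seq(0, 60, by = 1))
  expect_equal(gt$rate[!is.na(gt$rate)],
               rep(60, sum(!is.na(gt$rate))))
  gt <- ground_truth_hr(seq(0, 60, by = 0.75))
  expect_equal(unique(stats::na.omit(gt$rate)), 80)

  # jittered beats equal a brute-force rolling mean
  set.seed(31)
  bt <- cumsum(stats::runif(50, 0.6, 0.9))
  gt <- ground_truth_hr(bt)
  inst <- 60 / diff(bt)
  for (i in 30:49) {
    expect_equal(gt$rate[i], mean(inst[(i - 29):i]), tolerance = 1e-9)
  }
})

test_that("rate estimators are invariant to a global time shift", {
  per <- rep(c(0.6, 0.8), 25)
  ps1 <- list(times = cumsum(per), periods = per)
  ps2 <- list(times = cumsum(per) + 1000, periods = per)
  expect_equal(event_hr(ps1)$rate, event_hr(ps2)$rate)
  s1 <- make_stream(t = c(2, 5, 8), h = rep(60, 3))
  s2 <- make_stream(t = c(2, 5, 8) + 500, h = rep(60, 3))
  expect_equal(breath_to_breath_rr(s1)$rate, breath_to_breath_rr(s2)$rate)
})
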