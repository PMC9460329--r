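test_that("split respiratory events merge exactly per the reassignment table", {
  # gap of 60 samples (>= 20): unchanged
  s <- make_stream(t = c(3.0, 4.05), h = c(60, 150),
                   v1 = c(3000, 2000), v2 = c(1500, 500))
  out <- merge_split_respiratory(s)
  expect_equal(out$t, s$t)
  expect_equal(out$h, s$h)

  # gap of 18 samples (< 20): cardiac blip + merged respiratory event
  s <- make_stream(t = c(3.0, 3.84), h = c(60, 150),
                   v1 = c(3000, 2000), v2 = c(1500, 500))
  out <- merge_split_respiratory(s)
  expect_equal(nrow(out), 2L)
  # blip: H = P*N = 18, ends where E2 begins, V fields per the table
  expect_equal(out$h[1], 18)
  expect_equal(out$t[1], 3.09)
  expect_equal(out$v1[1], 2000)          # V1 of E2
  expect_equal(out$v2[1], 1500)          # V2 of E1
  # merged breath: H = H1 + H2, T = T2, V1 of E1, V2 of E2
  expect_equal(out$h[2], 210)
  expect_equal(out$t[2], 3.84)
  expect_equal(out$v1[2], 3000)
  expect_equal(out$v2[2], 500)
})

test_that("chained splits collapse to one breath and conserve total H", {
  # three long events each separated by < 20 samples
  # (gaps: 10 and 12 samples)
  s <- make_stream(t = c(1.0, 1.50, 1.985), h = c(80, 90, 85))
  out <- merge_split_respiratory(s)
  resp <- out[out$h > 20, ]
  expect_equal(nrow(resp), 1L)
  expect_equal(resp$h, 80 + 90 + 85)     # merging conserves H
  expect_equal(resp$t, 1.985)
  expect_equal(sum(out$h <= 20), 2L)     # one blip per interruption
  expect_equal(out$h[out$h <= 20], c(10, 12))

  # pairs involving a short event are left alone
  s2 <- make_stream(t = c(1.0, 1.06), h = c(80, 10))
  expect_equal(merge_split_respiratory(s2)$h, c(80, 10))
})

test_that("classification thresholds H and partitions the stream", {
  s <- make_stream(t = c(1, 2, 3, 4), h = c(21, 20, 300, 5))
  ce <- classify_events(s)
  expect_equal(ce$respiratory$h, c(21, 300))
  expect_equal(ce$cardiac$h, c(20, 5))

  empty <- classify_events(event_stream(sample_rate_hz = 200))
  expect_equal(nrow(empty$respiratory), 0L)
  expect_equal(nrow(empty$cardiac), 0L)

  # partition equals a brute-force filter on a mixed synthetic stream
  out <- generate_band_signal(synthetic_config(duration_s = 30, seed = 6))
  ev <- merge_split_respiratory(generate_events(out$series, 10))
  ce <- classify_events(ev)
  expect_equal(ce$respiratory$t, ev$t[ev$h > 20])
  expect_equal(ce$cardiac$t, ev$t[ev$h <= 20])
})

test_that("false-positive rejection drops the smaller-H event and is idempotent", {
  # two cardiac events 0.2 s apart (< 1/3 s): H = 5 is dropped
  ce <- classify_events(make_stream(t = c(1.0, 1.2), h = c(5, 9)))
  out <- reject_false_positives(ce)
  expect_equal(out$cardiac$h, 9)

  # two respiratory events 1.5 s apart: both kept
  ce <- classify_events(make_stream(t = c(1.0, 2.5), h = c(50, 60)))
  out <- reject_false_positives(ce)
  expect_equal(nrow(out$respiratory), 2L)

  # cardiac triplet 0.0/0.2/0.4 with H 9/5/7: sweep keeps 9 and 7
  ce <- classify_events(make_stream(t = c(1.0, 1.2, 1.4), h = c(9, 5, 7)))
  out <- reject_false_positives(ce)
  expect_equal(out$cardiac$h, c(9, 7))

  # idempotence and minimum-gap postcondition on random streams
  set.seed(11)
  for (i in 1:20) {
    n <- 40
    t_idx <- sort(sample.int(4000, n))
    h <- pmin(sample.int(18, n, replace = TRUE), c(t_idx[1], diff(t_idx)))
    ce <- classify_events(make_stream(t_idx / 200, h))
    once <- reject_false_positives(ce)
    twice <- reject_false_positives(once)
    expect_equal(twice$cardiac$t, once$cardiac$t)
    if (nrow(once$cardiac) > 1) {
      expect_true(all(diff(once$cardiac$t) >= 1 / 3 - 1e-12))
    }
  }
})

test_that("breath consolidation recovers crest-anchored breath events", {
  out <- generate_band_signal(synthetic_config(duration_s = 120, seed = 13))
  ev <- generate_events(out$series, 10)
  br <- consolidate_breaths(ev)
  truth <- out$truth$breath_peak_times
  rep <- match_events(br$t - br$h / 200, truth, 0.25)
  expect_gte(rep$sensitivity, 95)
  expect_gte(rep$precision, 95)
  # consolidated spans never overlap and are breath-scale
  expect_true(all(br$h > 20))
  expect_true(all(diff(br$t) >= 1))
})
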