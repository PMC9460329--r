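test_that("bucket index follows the fixed threshold array", {
  expect_equal(bucket_index(0.67), 5L)      # the 0.7 s bucket
  expect_equal(bucket_index(0.40), 1L)      # boundary: first threshold
  expect_equal(bucket_index(3.2), 14L)      # boundary: last threshold
  expect_equal(bucket_index(5.0), 14L)      # beyond range clamps
  expect_equal(bucket_index(0.1), 1L)
  expect_equal(bucket_index(c(0.45, 0.4501)), c(2L, 3L))
  expect_error(bucket_index(0), "positive")
})

test_that("streamed bucket state equals a from-scratch histogram", {
  set.seed(3)
  st <- bucket_state()
  periods <- stats::runif(50, 0.3, 3.6)
  for (i in seq_along(periods)) {
    st <- bucket_update(st, periods[i])
    want <- brute_bucket_counts(periods[1:i], st$thresholds)
    expect_identical(st$counts, as.integer(want$counts))
    expect_equal(st$means, want$means, tolerance = 1e-9)
    expect_equal(sum(st$counts), length(st$fifo))
    expect_lte(length(st$fifo), 30L)
  }
  expect_error(bucket_update(st, -1), "positive")
})

test_that("majority rules fire in priority order and match exhaustive search", {
  # single majority: any counter > 20
  st <- bucket_state()
  for (i in 1:21) st <- bucket_update(st, 0.85)   # bucket 7 (0.9)
  maj <- bucket_majority(st)
  expect_equal(maj$index, 7L)
  expect_equal(maj$rule, "single")
  expect_equal(maj$mean, 0.85, tolerance = 1e-9)

  # dual majority: two adjacent buckets sum > 15, none > 20
  st <- bucket_state()
  for (i in 1:9) st <- bucket_update(st, 0.68)    # bucket 5
  for (i in 1:8) st <- bucket_update(st, 0.75)    # bucket 6
  maj <- bucket_majority(st)
  expect_equal(maj$rule, "dual")
  expect_equal(sort(maj$window), c(5L, 6L))
  expect_equal(maj$mean, (9 * 0.68 + 8 * 0.75) / 17, tolerance = 1e-9)

  # no rule fires on a thin spread
  st <- bucket_state()
  for (p in seq(0.42, 3.1, length.out = 12)) st <- bucket_update(st, p)
  expect_null(bucket_majority(st))

  # random states match the exhaustive scan
  set.seed(9)
  for (case in 1:100) {
    st <- bucket_state()
    for (p in stats::runif(30, 0.35, 3.4)) st <- bucket_update(st, p)
    got <- bucket_majority(st)
    want <- brute_majority(st$counts, st$means)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$index, want$index)
      expect_equal(got$mean, want$mean, tolerance = 1e-9)
    }
  }
})

test_that("bucket HR folds harmonic buckets in and repeats last valid output", {
  # all 30 elements at 0.70 s -> 85.71 bpm
  st <- bucket_state()
  for (i in 1:30) st <- bucket_update(st, 0.70)
  res <- bucket_hr(st)
  expect_equal(res$hr, 60 / 0.7, tolerance = 1e-6)

  # majority at 0.70 plus 5 elements at 1.40: 1.40/2 folds in, HR unchanged
  st <- bucket_state()
  for (i in 1:25) st <- bucket_update(st, 0.70)
  for (i in 1:5) st <- bucket_update(st, 1.40)
  res <- bucket_hr(st)
  expect_equal(res$hr, 60 / 0.7, tolerance = 1e-6)

  # majority at 0.70 plus 4 elements at 2.8: neither /2 nor /3 is within
  # 20 bpm of 85.7 -> excluded
  st <- bucket_state()
  for (i in 1:26) st <- bucket_update(st, 0.70)
  for (i in 1:4) st <- bucket_update(st, 2.8)
  res <- bucket_hr(st)
  expect_equal(res$hr, 60 / 0.7, tolerance = 1e-6)

  # no majority: repeats the last valid output; absent when none exists
  st0 <- bucket_state()
  expect_true(is.na(bucket_hr(st0)$hr))
  st1 <- res$state
  st1$counts <- rep(2L, 14); st1$means <- rep(1, 14)
  st1$fifo <- rep(1, 28)
  expect_equal(bucket_hr(st1)$hr, res$hr)
})

test_that("bucketing stream recovers constant HR with 30% doubled periods", {
  set.seed(17)
  per <- rep(0.7, 200)
  per[stats::runif(200) < 0.3] <- 1.4
  out <- bucket_hr_stream(per)
  tail_hr <- out$hr[100:200]
  expect_true(all(abs(tail_hr - 60 / 0.7) < 2))
})
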