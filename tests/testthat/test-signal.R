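test_that("low-pass filter has unit DC gain and the expected frequency response", {
  t <- (0:299) / 30
  # constant trajectory passes through exactly
  f0 <- lowpass(constant_track(5, 300))
  expect_lt(max(abs(f0$data - 5)), 1e-9)
  # 2 Hz passband sine preserved within 2% (interior of the record)
  f2 <- lowpass(signal_track(sin(2 * pi * 2 * t)))
  mid <- 30:270
  expect_equal(max(abs(f2$data[mid, 1, 1])), max(abs(sin(2 * pi * 2 * t)[mid])),
               tolerance = 0.02)
  # 12 Hz stopband sine attenuated below 10%
  f12 <- lowpass(signal_track(sin(2 * pi * 12 * t)))
  expect_lt(max(abs(f12$data[mid, 1, 1])), 0.1)
  # Nyquist violation
  expect_error(lowpass(constant_track(1), cutoff = 20), "Nyquist")
})

test_that("low-pass filter is idempotent for band-limited signals and skips short runs", {
  t <- (0:299) / 30
  tr <- signal_track(sin(2 * pi * 1.5 * t) + 0.5 * cos(2 * pi * 2.5 * t))
  once <- lowpass(tr)
  twice <- lowpass(once)
  mid <- 30:270
  expect_equal(twice$data[mid, 1, 1], once$data[mid, 1, 1], tolerance = 0.02)

  # visible runs shorter than 3 fs / cutoff samples pass through unfiltered
  vis <- matrix(TRUE, 300, 21)
  vis[16:300, 3] <- FALSE  # leaves a 15-sample run for landmark 3
  spiky <- track3d(array(rep(sin(2 * pi * 12 * t), 21 * 3), c(300, 21, 3)),
                   visible = vis, fs = 30)
  f <- lowpass(spiky)
  expect_equal(f$data[1:15, 3, 1], spiky$data[1:15, 3, 1])
  expect_identical(f$visible, spiky$visible)
})

test_that("resampling interpolates linearly and gates visibility", {
  ramp <- seq(0, 99)
  tr <- track3d(array(rep(ramp, 21 * 3), c(100, 21, 3)), fs = 100)
  r <- resample_track(tr, 30)
  t_out <- (seq_len(dim(r$data)[1]) - 1) / 30
  expect_equal(r$data[, 1, 1], t_out * 100, tolerance = 1e-9)

  # resampling to the same aligned grid is the identity
  same <- resample_track(tr, 100)
  expect_equal(same$data, tr$data, tolerance = 1e-12)

  # a target sample bracketed by a gap frame is invisible
  vis <- matrix(TRUE, 100, 21)
  vis[50:60, 2] <- FALSE   # source frames 50..60 missing
  tr2 <- track3d(array(rep(ramp, 21 * 3), c(100, 21, 3)), visible = vis, fs = 100)
  r2 <- resample_track(tr2, 30)
  t_out2 <- (seq_len(dim(r2$data)[1]) - 1) / 30
  src_frame <- t_out2 * 100 + 1   # fractional source frame index
  in_gap <- src_frame > 49 & src_frame < 61
  expect_false(any(r2$visible[in_gap, 2]))
  expect_true(all(r2$visible[!in_gap, 2]))
})

test_that("double resampling reproduces band-limited signals", {
  t <- (0:199) / 100
  x <- sin(2 * pi * 2 * t)
  tr <- signal_track(x, fs = 100)
  back <- resample_track(resample_track(tr, 30), 100)
  n <- dim(back$data)[1]
  # linear-interpolation error bound at the 30 Hz stage: (2 pi f / fs)^2 / 8
  bound <- (2 * pi * 2 / 30)^2 / 8
  expect_lt(max(abs(back$data[, 1, 1] - x[seq_len(n)])), 1.1 * bound)
})

test_that("gap filling interpolates short gaps only and flags provenance", {
  t <- (0:299) / 30
  x <- sin(2 * pi * 1 * t)
  vis <- matrix(TRUE, 300, 21)
  vis[100:102, 1] <- FALSE   # 0.1 s gap
  vis[150:200, 2] <- FALSE   # 1.7 s gap, beyond max_gap
  tr <- track3d(array(rep(x, 21 * 3), c(300, 21, 3)), visible = vis, fs = 30)
  g <- fill_gaps(tr, max_gap_s = 0.5)
  expect_lt(max(abs(g$data[100:102, 1, 1] - x[100:102])), 1)
  expect_true(all(g$interpolated[100:102, 1]))
  expect_true(all(g$visible[100:102, 1]))
  expect_true(all(is.nan(g$data[150:200, 2, 1])))
  # no gaps: identity
  full <- track3d(array(rep(x, 21 * 3), c(300, 21, 3)), fs = 30)
  expect_identical(fill_gaps(full, 0.5)$data, full$data)
})

test_that("lag estimation recovers constructed shifts and rejects flat series", {
  t <- (0:299) / 30
  a <- sin(2 * pi * 0.5 * t) + 0.3 * sin(2 * pi * 1.1 * t)
  for (k in c(-9, 0, 7)) {
    b <- if (k >= 0) c(rep(a[1], k), a)[seq_along(a)]
         else c(a[(-k + 1):length(a)], rep(a[length(a)], -k))
    expect_equal(as.integer(estimate_lag(a, b, 30)), k)
  }
  expect_error(estimate_lag(rep(1, 300), rep(2, 300), 30), "no signal")
})

test_that("lag estimation on white noise shows no systematic bias", {
  lags <- sapply(1:20, function(s) {
    set.seed(s)
    as.integer(estimate_lag(stats::rnorm(300), stats::rnorm(300), 30))
  })
  # chance-level: mean lag well inside the +/-60-frame search window
  expect_lt(abs(mean(lags)), 25)
})
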