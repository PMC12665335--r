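test_that("pitch tracker recovers a constant 440 Hz tone within 1%", {
  wav <- synthesize_audio(rep(440, 200), 1, sample_rate = 16000)
  pt <- estimate_f0(wav, 16000)
  expect_gt(mean(pt$voiced), 0.8)
  expect_lt(abs(median(pt$f0[pt$voiced]) - 440) / 440, 0.01)
})

test_that("pitch tracker follows a 200 to 400 Hz glide monotonically", {
  contour <- seq(200, 400, length.out = 300)
  wav <- synthesize_audio(contour, 1, sample_rate = 16000)
  pt <- estimate_f0(wav, 16000)
  f0 <- pt$f0[pt$voiced]
  expect_gt(length(f0), 100)
  # smoothed track increases over its run and spans the glide
  expect_gt(cor(seq_along(f0), f0), 0.98)
  expect_lt(abs(min(f0) - 200) / 200, 0.1)
  expect_lt(abs(max(f0) - 400) / 400, 0.1)
})

test_that("silence yields no voiced frames, with a warning", {
  expect_warning(pt <- estimate_f0(numeric(8000), 16000), "no voiced")
  expect_false(any(pt$voiced))
})

test_that("short interior pitch gaps are bridged linearly, long ones flagged", {
  rate <- 100
  f0 <- c(rep(100, 10), rep(NA, 20), rep(110, 10))     # 200 ms gap
  voiced <- !is.na(f0)
  out <- interpolate_gaps(f0, voiced, rate)
  expect_true(out$ok)
  expect_true(all(out$voiced))
  # linear bridge between 100 at frame 10 and 110 at frame 31
  expect_equal(out$f0[11:30], 100 + 10 * (11:30 - 10) / 21)
  mid <- out$f0[c(20, 21)]                             # midpoint ~ 105 Hz
  expect_true(all(abs(mid - 105) < 0.5))

  f0_long <- c(rep(100, 10), rep(NA, 50), rep(110, 10))  # 500 ms gap
  out2 <- interpolate_gaps(f0_long, !is.na(f0_long), rate)
  expect_false(out2$ok)
  expect_true(all(is.na(out2$f0[11:60])))

  gapless <- interpolate_gaps(rep(100, 30), rep(TRUE, 30), rate)
  expect_true(gapless$ok)
  expect_equal(gapless$f0, rep(100, 30))

  # edge gaps are not interior: untouched, not flagged
  edge <- interpolate_gaps(c(NA, NA, rep(100, 10)), c(FALSE, FALSE, rep(TRUE, 10)), rate)
  expect_true(edge$ok)
  expect_true(is.na(edge$f0[1]))
})

test_that("Gaussian smoothing preserves constants and reproduces the kernel", {
  expect_equal(smooth_gaussian(rep(7.7, 40)), rep(7.7, 40))
  # interior unit impulse maps to the normalised kernel
  sigma <- 2.5; r <- ceiling(4 * sigma)
  n <- 60
  x <- numeric(n); x[30] <- 1
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  out <- smooth_gaussian(x, sigma)
  expect_equal(out[(30 - r):(30 + r)], k, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-9)          # mass preserved
  # convex combination: output range within input range
  set.seed(3)
  y <- rnorm(100)
  sy <- smooth_gaussian(y)
  expect_gte(min(sy), min(y) - 1e-9)
  expect_lte(max(sy), max(y) + 1e-9)
})

test_that("estimated pitch derivative matches its defining formula", {
  expect_equal(delta_f0(rep(5, 10)), rep(0, 10))
  # linear ramp of slope c gives c everywhere
  expect_equal(delta_f0(3.5 * (1:20)), rep(3.5, 20))
  # direct evaluation on a worked example
  d <- delta_f0(c(0, 1, 4, 9))
  expect_equal(d[3], ((4 - 1) + (9 - 1) / 2) / 2)      # 3.5
  expect_equal(d[2], ((1 - 0) + (4 - 0) / 2) / 2)
  expect_equal(d[1], d[2])                             # endpoint replication
  expect_equal(d[4], d[3])
  expect_error(delta_f0(c(1, 2)), "at least 3")
})

test_that("loudness is 0 dB at the reference and -10 dB a decade below", {
  # two-segment tone: second half at 10x the power (amplitude sqrt(10)) -- but
  # envelopes are capped at 1, so scale the first half down instead
  env <- c(rep(1 / sqrt(10), 150), rep(1, 150))
  wav <- synthesize_audio(rep(300, 300), env, sample_rate = 16000)
  L <- loudness(wav, 16000)
  expect_lte(max(L), 0)
  expect_equal(max(L), 0)                              # reference frame at 0 dB
  n <- length(L)
  first <- L[10:floor(n * 0.4)]                        # interior of the quiet half
  expect_lt(abs(median(first) - (-10)), 1)
  expect_warning(L0 <- loudness(numeric(1000), 16000), "silent")
  expect_true(all(L0 == -80))
})

test_that("loudness tracks the squared amplitude envelope", {
  env <- seq(0.1, 1, length.out = 300)
  wav <- synthesize_audio(rep(250, 300), env, sample_rate = 16000)
  L <- loudness(wav, 16000)
  n <- length(L)
  idx <- 5:(n - 5)
  expected <- 20 * log10(seq(0.1, 1, length.out = n))
  expect_lt(max(abs(L[idx] - (expected[idx] - max(expected)))), 1)
})

test_that("spectral centroid matches closed-form weighted means", {
  sr <- 16000
  t <- (0:15999) / sr
  # single sinusoid: centroid at f within a bin width
  x <- sin(2 * pi * 1000 * t)
  cen <- spectral_centroid(x, sr)
  binw <- sr / 1024
  expect_lt(abs(median(cen) - 1000), 2 * binw)
  # two equal components: centroid near the midpoint
  y <- sin(2 * pi * 500 * t) + sin(2 * pi * 1500 * t)
  expect_lt(abs(median(spectral_centroid(y, sr)) - 1000), 2 * binw)
  # harmonic complex with known magnitudes: brute-force weighted mean of the
  # actual spectrum of one frame
  z <- sin(2 * pi * 400 * t) + 0.5 * sin(2 * pi * 800 * t) +
    0.25 * sin(2 * pi * 1200 * t)
  frame <- z[1:736] * (0.5 - 0.5 * cos(2 * pi * (0:735) / 735))
  X <- abs(fft(c(frame, numeric(1024 - 736)))[1:513])
  X[X < 0.05 * max(X)] <- 0                            # same leakage gate
  freqs <- (0:512) * sr / 1024
  expect_lt(abs(median(spectral_centroid(z, sr)) - sum(freqs * X) / sum(X)),
            2 * binw)
})

test_that("centroid of silent frames carries the previous defined value", {
  sr <- 16000
  x <- c(sin(2 * pi * 700 * (0:7999) / sr), numeric(8000))
  cen <- spectral_centroid(x, sr)
  und <- attr(cen, "undefined")
  expect_true(any(und))
  last_def <- max(which(!und))
  expect_true(all(cen[und & seq_along(cen) > last_def] == cen[last_def]))
})

test_that("the full sonic chain produces a consistent feature bundle", {
  contour <- 220 * 2^(0.3 * sin(seq(0, 3 * pi, length.out = 250)))
  wav <- synthesize_audio(contour, 0.9, sample_rate = 16000)
  sf <- extract_sonic_features(wav, 16000)
  expect_s3_class(sf, "sonic_features")
  expect_true(sf$ok)
  n <- length(sf$f0)
  expect_equal(length(sf$delta_f0), n)
  expect_equal(length(sf$loudness), n)
  expect_equal(length(sf$centroid), n)
  expect_true(all(sf$loudness <= 0))
  expect_true(all(sf$f0 > 0))
  expect_true(all(sf$centroid >= 0 & sf$centroid <= 8000))
  # median recovered pitch within 2% of the median of the true contour
  expect_lt(abs(median(sf$f0) - median(contour)) / median(contour), 0.02)
  # rerunning is deterministic
  sf2 <- extract_sonic_features(wav, 16000)
  expect_identical(sf$f0, sf2$f0)
})
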