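test_that("ratio-of-ratios arithmetic and guards", {
  expect_equal(compute_ratio(0.02, 2.0, 0.02, 2.0), 1.0)
  expect_equal(compute_ratio(0.01, 1.0, 0.02, 1.0), 0.5)
  expect_error(compute_ratio(0.01, 1.0, 0.02, 0), "positive")
  expect_error(compute_ratio(-0.01, 1.0, 0.02, 1.0), "positive")
})

test_that("the empirical calibration maps, clamps, and decreases", {
  expect_equal(spo2_from_ratio(0.5), 97.5)
  expect_equal(spo2_from_ratio(0.0), 100)   # raw 110, clamped
  expect_equal(spo2_from_ratio(1.6), 70)
  expect_equal(spo2_from_ratio(4.4), 0)
  expect_error(spo2_from_ratio(-0.1), "non-negative")
  # strictly decreasing wherever the line is not clamped
  r <- seq(0.4, 4.4, by = 0.05)
  expect_true(all(diff(spo2_from_ratio(r)) < 0))
  # weakly decreasing overall
  r_all <- seq(0, 5, by = 0.05)
  expect_true(all(diff(spo2_from_ratio(r_all)) <= 0))
})

test_that("pulse detection counts beats, ignores flats, honours refractory", {
  s <- synthesize_stream(physio_profile(heart_rate = 75, noise_sd = 0),
                         duration = 8)
  b <- ambient_correct(demultiplex(s))
  cp <- extract_components(b$infrared, b$fs_channel)
  n <- length(detect_pulses(cp$ac, b$fs_channel))
  expect_gte(n, 9)
  expect_lte(n, 11)

  expect_length(detect_pulses(rep(1, 500), 125), 0)
  expect_length(detect_pulses(numeric(0), 125), 0)

  # two identical peaks 0.1 s apart: refractory keeps the earlier one
  x <- numeric(250)
  x[c(100, 112)] <- 1
  expect_equal(detect_pulses(x, 125), 100)
})

test_that("heart-rate arithmetic follows samples-per-pulse", {
  expect_equal(heart_rate(125, 100, 1), 75)
  expect_equal(heart_rate(125, 250, 2), 60)
  expect_true(is.na(heart_rate(125, 100, 0)))
  s <- synthesize_stream(physio_profile(heart_rate = 72, seed = 8),
                         duration = 16)
  v <- estimate_vitals(s)
  expect_equal(mean(v$heart_rate[v$t >= 10]), 72, tolerance = 2 / 72)
})

test_that("perfusion index is the AC/DC contrast in percent", {
  expect_equal(perfusion_index(0.02, 2.0), 1.0)
  expect_equal(perfusion_index(0, 2.0), 0)
  expect_error(perfusion_index(0.02, 0), "positive")
  s <- synthesize_stream(physio_profile(perfusion_index = 2, noise_sd = 0),
                         duration = 16)
  v <- estimate_vitals(s)
  expect_equal(mean(v$perfusion_index[v$t >= 10]), 2, tolerance = 0.1)
})

test_that("weighted moving average normalizes, truncates, and bounds", {
  expect_equal(smooth_wma(rep(7, 5)), 7)
  expect_equal(smooth_wma(c(90, 100), weights = c(1, 3)), 97.5)
  expect_equal(smooth_wma(42, weights = 1:5), 42)
  expect_error(smooth_wma(numeric(0)), "non-empty")
  expect_error(smooth_wma(1:3, weights = c(1, -1, 2)), "positive")
  set.seed(1)
  for (k in 1:20) {
    h <- runif(sample(1:8, 1), 80, 100)
    w <- runif(5, 0.1, 2)
    v <- smooth_wma(h, w)
    expect_gte(v, min(h) - 1e-9)
    expect_lte(v, max(h) + 1e-9)
  }
})

test_that("noise-free streams over the grid are recovered within tolerance", {
  for (spo2 in c(80, 85, 90, 94, 98)) {
    for (hr in c(50, 75, 120)) {
      s <- synthesize_stream(physio_profile(spo2 = spo2, heart_rate = hr,
                                            noise_sd = 0), duration = 16)
      v <- estimate_vitals(s)
      post <- v[v$t >= 10 & v$valid, ]
      expect_gt(nrow(post), 0)
      expect_lt(max(abs(post$spo2 - spo2)), 1,
                label = sprintf("spo2 error at (%g, %g)", spo2, hr))
      expect_lt(max(abs(post$heart_rate - hr)), 2,
                label = sprintf("hr error at (%g, %g)", spo2, hr))
    }
  }
})

test_that("the reader emits one record per whole second", {
  s <- synthesize_stream(physio_profile(seed = 21), duration = 12.7)
  v <- estimate_vitals(s)
  expect_equal(nrow(v), 12)
  expect_equal(v$t, 0:11)

  s60 <- synthesize_stream(physio_profile(spo2 = 94, seed = 22), duration = 60)
  v60 <- estimate_vitals(s60)
  expect_equal(nrow(v60), 60)
  expect_true(all(v60$valid))
  expect_lt(max(abs(v60$spo2[v60$t >= 10] - 94)), 1)
})

test_that("signal loss invalidates records and clears the vitals fields", {
  s <- inject_artifacts(
    synthesize_stream(physio_profile(seed = 23), duration = 15),
    list(list(type = "no_finger", start = 5, end = 8)))
  v <- estimate_vitals(s)
  expect_true(all(!v$valid[v$t %in% 5:7]))
  expect_true(all(is.na(v$spo2[!v$valid])))
  expect_true(all(is.na(v$heart_rate[!v$valid])))
  # detection and re-lock lag of at most one second on either side
  expect_true(all(v$valid[v$t <= 4]))
  expect_true(all(v$valid[v$t >= 9]))
})

test_that("a motion burst does not destroy the post-burst estimates", {
  s <- inject_artifacts(
    synthesize_stream(physio_profile(spo2 = 94, seed = 24), duration = 20),
    list(list(type = "motion", start = 5, end = 8, amplitude = 0.05,
              freq = 50)))
  v <- estimate_vitals(s)
  late <- v[v$t >= 14 & v$valid, ]
  expect_gt(nrow(late), 3)
  expect_lt(max(abs(late$spo2 - 94)), 1.5)
})
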