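test_that("synthesized streams embed the target ratio-of-ratios exactly", {
  for (spo2 in c(85, 97.5, 80)) {
    s <- synthesize_stream(physio_profile(spo2 = spo2, noise_sd = 0),
                           duration = 4)
    cm <- s$components
    red_idx <- s$slot == "RED_ON"
    ir_idx <- s$slot == "IR_ON"
    pp <- function(x) diff(range(x))
    r_embedded <- (pp(cm$ac[red_idx]) / mean(cm$base[red_idx] - s$profile$ambient_level)) /
      (pp(cm$ac[ir_idx]) / mean(cm$base[ir_idx] - s$profile$ambient_level))
    expect_equal(r_embedded, (110 - spo2) / 25, tolerance = 1e-3)
  }
})

test_that("round-trip through demux and the filter chain recovers R", {
  s <- synthesize_stream(physio_profile(spo2 = 85, noise_sd = 0), duration = 16)
  v <- estimate_vitals(s)
  expect_equal(mean(v$r_ratio[v$t >= 10]), 1.0, tolerance = 1e-3)
})

test_that("stream sizes follow the slot arithmetic", {
  s <- synthesize_stream(physio_profile(noise_sd = 0), duration = 10)
  expect_length(s$samples, 5000)
  b <- demultiplex(s)
  # slot-counting oracle: 10 s x 500 S/s, one red sample per 4-slot cycle
  expect_length(b$red, count_slots(5000, "RED_ON"))
  expect_length(b$red, 1250)
  # both-off slots carry ambient only
  off <- s$slot == "BOTH_OFF"
  expect_equal(max(abs(s$samples[off] - s$profile$ambient_level)), 0)
})

test_that("identical profile and seed give bit-identical streams", {
  a <- synthesize_stream(physio_profile(seed = 11), duration = 3)
  b <- synthesize_stream(physio_profile(seed = 11), duration = 3)
  expect_identical(a$samples, b$samples)
  c2 <- synthesize_stream(physio_profile(seed = 12), duration = 3)
  expect_false(identical(a$samples, c2$samples))
})

test_that("the dominant AC spectral peak sits at the heart rate", {
  for (hr in c(48, 75, 132)) {
    s <- synthesize_stream(physio_profile(heart_rate = hr, noise_sd = 0),
                           duration = 16)
    ir <- s$components$ac[s$slot == "IR_ON"]
    fs_ch <- s$sample_rate / 4
    spec <- Mod(stats::fft(ir))[2:(length(ir) / 2)]
    f_peak <- which.max(spec) / (length(ir) / fs_ch)
    expect_lt(abs(f_peak - hr / 60), 1 / (length(ir) / fs_ch) + 1e-9)
  }
})

test_that("profile validation rejects out-of-range physiology", {
  expect_error(physio_profile(spo2 = 65), "spo2")
  expect_error(physio_profile(heart_rate = 300), "heart_rate")
  expect_error(physio_profile(perfusion_index = 0), "perfusion_index")
  expect_error(physio_profile(dc_ir = -1), "dc_ir")
  expect_error(synthesize_stream(physio_profile(), duration = 0), "duration")
  expect_error(synthesize_stream(physio_profile(), 1, sample_rate = 402),
               "multiple of 4")
})

test_that("no-finger artifacts blank the signal and the truth flags", {
  s <- synthesize_stream(physio_profile(seed = 4), duration = 10)
  s2 <- inject_artifacts(s, list(list(type = "no_finger", start = 5, end = 8)))
  tr <- truth_series(s2)
  expect_identical(tr$valid, !(tr$t %in% 5:7))
  t_samp <- (seq_along(s2$samples) - 1) / s2$sample_rate
  gap <- t_samp >= 5 & t_samp < 8
  expect_equal(s2$components$ac[gap], rep(0, sum(gap)))
  expect_equal(s2$components$base[gap],
               rep(s$profile$ambient_level, sum(gap)))
  # samples outside the event are untouched
  expect_identical(s2$samples[!gap], s$samples[!gap])
})

test_that("empty and zero-amplitude artifact specs are identities", {
  s <- synthesize_stream(physio_profile(seed = 4), duration = 5)
  expect_identical(inject_artifacts(s, list())$samples, s$samples)
  s3 <- inject_artifacts(s, list(list(type = "motion", start = 1, end = 3,
                                      amplitude = 0)))
  expect_identical(s3$samples, s$samples)
})

test_that("overlapping same-type artifact intervals are rejected", {
  s <- synthesize_stream(physio_profile(seed = 4), duration = 10)
  expect_error(inject_artifacts(s, list(
    list(type = "no_finger", start = 2, end = 5),
    list(type = "no_finger", start = 4, end = 6))), "overlap")
  # different types may overlap
  expect_silent(inject_artifacts(s, list(
    list(type = "no_finger", start = 2, end = 5),
    list(type = "drift", start = 4, end = 6, slope = 0.01))))
})

test_that("truth series has one record per second and tracks schedules", {
  s <- synthesize_stream(physio_profile(seed = 1), duration = 60)
  expect_equal(nrow(truth_series(s)), 60)
  expect_equal(nrow(unique(truth_series(s)[, -1])), 1)

  sched <- data.frame(t = 30, spo2 = 96)
  s2 <- synthesize_stream(physio_profile(spo2 = 92, seed = 1), duration = 60,
                          schedule = sched)
  tr <- truth_series(s2)
  expect_equal(tr$spo2[tr$t < 30], rep(92, 30))
  expect_equal(tr$spo2[tr$t >= 30], rep(96, 30))
})

test_that("stream CSV serialization round-trips", {
  s <- synthesize_stream(physio_profile(seed = 2), duration = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, path)
  s2 <- read_stream_csv(path)
  expect_identical(s2$samples, s$samples)
  expect_identical(s2$slot, s$slot)
})
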