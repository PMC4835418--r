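rec1 <- function(t = 0) {
  data.frame(t = t, spo2 = 95.5, heart_rate = 74.2, perfusion_index = 2.01,
             valid = TRUE, r_ratio = 0.58)
}

test_that("a lossless link delivers every record in order", {
  link <- transport_link(drop_prob = 0)
  seen <- numeric(0)
  for (t in 0:49) {
    out <- transmit(link, rec1(t))
    link <- out$link
    expect_true(out$delivered)
    seen <- c(seen, out$record$t)
  }
  expect_equal(seen, 0:49)
  expect_equal(link$delivered, 50L)
  expect_equal(link$dropped, 0L)
})

test_that("drop counts are reproducible under a fixed seed", {
  count <- function() {
    link <- transport_link(drop_prob = 0.5)
    for (i in 1:1000) link <- transmit(link, rec1(i))$link
    c(link$delivered, link$dropped)
  }
  set.seed(31); a <- count()
  set.seed(31); b <- count()
  expect_identical(a, b)
  expect_equal(sum(a), 1000L)
  expect_gt(a[1], 350)
  expect_lt(a[1], 650)
})

test_that("total transport loss trips the watchdog and closes the valve", {
  cfg <- session_config(duration = 150, seed = 5,
                        transport = transport_link(drop_prob = 1))
  ses <- run_closed_loop(cfg)
  expect_equal(ses$commands$reason, "watchdog_stop")
  expect_equal(ses$commands$t, 61)
  expect_equal(ses$commands$flow, 0)
  expect_true(all(ses$patient$flow_in == 0))
})

test_that("closed-loop sessions keep the per-second record cadence", {
  ses <- run_closed_loop(session_config(duration = 120, seed = 9))
  expect_equal(nrow(ses$vitals), 120)
  expect_equal(ses$vitals$t, 0:119)
  expect_equal(nrow(ses$patient), 120)
})

test_that("a session is fully determined by its config and seed", {
  cfg <- session_config(duration = 90, seed = 17,
                        transport = transport_link(drop_prob = 0.2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_session_logs(run_closed_loop(cfg), d1)
  write_session_logs(run_closed_loop(cfg), d2)
  for (f in c("vitals.csv", "commands.csv", "patient.csv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("every valve command is justified by a record or a stall", {
  ses <- run_closed_loop(session_config(duration = 400, seed = 13,
                                        no_finger = list(c(150, 170))))
  for (i in seq_len(nrow(ses$commands))) {
    cmd <- ses$commands[i, ]
    rec <- ses$vitals[ses$vitals$t == cmd$t, ]
    if (cmd$reason == "no_signal_stop") {
      expect_false(rec$valid)
    } else if (cmd$reason == "watchdog_stop") {
      expect_true(all(!ses$vitals$valid[ses$vitals$t > cmd$t - 61 &
                                          ses$vitals$t <= cmd$t]))
    } else {
      expect_true(rec$valid)
    }
  }
  # titration cadence holds in session logs too
  titr <- ses$commands[ses$commands$reason %in%
                         c("titrate_up", "titrate_down", "hold"), ]
  expect_true(all(diff(titr$t) >= 60))
})

test_that("vitals logs round-trip through CSV and JSONL", {
  s <- synthesize_stream(physio_profile(seed = 41), duration = 8)
  v <- estimate_vitals(inject_artifacts(
    s, list(list(type = "no_finger", start = 3, end = 5))))
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_vitals_log(v, path)
    v2 <- read_vitals_log(path)
    expect_equal(as.data.frame(v2), as.data.frame(v)[names(v2)],
                 tolerance = 0, label = ext)
  }
})

test_that("command and patient logs round-trip exactly", {
  ses <- run_closed_loop(session_config(duration = 130, seed = 3))
  pc <- withr::local_tempfile(fileext = ".csv")
  write_command_log(ses$commands, pc)
  expect_equal(read_command_log(pc), ses$commands, tolerance = 0)
  pp <- withr::local_tempfile(fileext = ".jsonl")
  write_patient_log(ses$patient, pp)
  expect_equal(read_patient_log(pp), ses$patient, tolerance = 0)
})

test_that("malformed logs raise parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,spo2", "0,95"), path)
  expect_error(read_vitals_log(path), "missing field")
  writeLines(c("t,spo2,heart_rate,perfusion_index,valid,r_ratio",
               "0,95,74,2,TRUE,oops"), path)
  expect_error(read_vitals_log(path), "r_ratio")
  # an empty file is an empty log, not an error
  writeLines(character(0), path)
  expect_equal(nrow(read_vitals_log(path)), 0)
})

test_that("session configs load from YAML with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("duration: 300",
               "seed: 4",
               "profile:",
               "  heart_rate: 80",
               "patient:",
               "  baseline_spo2: 88",
               "controller:",
               "  step: 1.0",
               "  band: [92, 96]"), path)
  cfg <- read_session_config(path)
  expect_equal(cfg$duration, 300)
  expect_equal(cfg$profile$heart_rate, 80)
  expect_equal(cfg$patient$baseline_spo2, 88)
  expect_equal(cfg$controller$step, 1.0)
  expect_equal(cfg$controller$band, c(92, 96))

  writeLines("bogus_key: 1", path)
  expect_error(read_session_config(path), "unknown config key")
  writeLines(c("profile:", "  spo2: 120"), path)
  expect_error(read_session_config(path), "spo2")
})

test_that("the command-line front end synthesizes and estimates", {
  cli <- system.file("exec", "oxloop", package = "oxloop")
  expect_true(nzchar(cli))
  # child processes must see the same library paths as this session
  lib_env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  stream_csv <- withr::local_tempfile(fileext = ".csv")
  vit_csv <- withr::local_tempfile(fileext = ".csv")
  out <- system2("Rscript", c(cli, "synth", "--out", stream_csv,
                              "--duration", "8", "--seed", "2"),
                 stdout = TRUE, stderr = TRUE, env = lib_env)
  expect_true(file.exists(stream_csv))
  out2 <- system2("Rscript", c(cli, "estimate", "--in", stream_csv,
                               "--out", vit_csv), stdout = TRUE, stderr = TRUE,
                 env = lib_env)
  v <- read_vitals_log(vit_csv)
  expect_equal(nrow(v), 8)
  # configuration errors exit with status 2
  status <- system2("Rscript", c(cli, "synth", "--out", stream_csv,
                                 "--spo2", "300"), stdout = FALSE,
                    stderr = FALSE, env = lib_env)
  expect_equal(status, 2)
})
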