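#' Ground-truth physiological profile for PPG synthesis
#'
#' Describes the "patient at the sensor" that the stream generator emulates:
#' the true oxygen saturation, heart rate and perfusion that a perfect reader
#' would recover, plus detector DC levels, ambient light and measurement noise.
#'
#' @param spo2 True arterial oxygen saturation, percent, in \[70, 100\].
#' @param heart_rate True heart rate, beats per minute, in \[30, 240\] (the
#'   cardiac fundamental must stay inside the 0.5--4.0 Hz PPG band).
#' @param perfusion_index True perfusion index, percent: the peak-to-peak
#'   pulsatile (AC) amplitude of the infra-red channel divided by its DC
#'   level, times 100. Must be positive.
#' @param dc_red,dc_ir Non-pulsatile detector levels of the red / infra-red
#'   channels (dimensionless A/D units), both positive.
#' @param noise_sd Standard deviation of additive white Gaussian noise applied
#'   to every acquisition slot (same units as the detector levels).
#' @param ambient_level Ambient-light level added to every slot; this is what
#'   the photodiode sees when both LEDs are off.
#' @param seed Optional integer seed making synthesis reproducible.
#' @return An object of class `physio_profile`.
#' @examples
#' p <- physio_profile(spo2 = 94, heart_rate = 80)
#' p$spo2
#' @export
physio_profile <- function(spo2 = 97, heart_rate = 75, perfusion_index = 2,
                           dc_red = 2, dc_ir = 2, noise_sd = 0.005,
                           ambient_level = 0.1, seed = NULL) {
  check_range(spo2, "spo2", 70, 100)
  check_range(heart_rate, "heart_rate", 30, 240)
  check_range(perfusion_index, "perfusion_index", 0, Inf, open_lo = TRUE)
  check_range(dc_red, "dc_red", 0, Inf, open_lo = TRUE)
  check_range(dc_ir, "dc_ir", 0, Inf, open_lo = TRUE)
  check_range(noise_sd, "noise_sd", 0, Inf)
  check_range(ambient_level, "ambient_level", 0, Inf)
  if (!is.null(seed)) check_range(seed, "seed", -2^31, 2^31)
  structure(list(spo2 = spo2, heart_rate = heart_rate,
                 perfusion_index = perfusion_index,
                 dc_red = dc_red, dc_ir = dc_ir, noise_sd = noise_sd,
                 ambient_level = ambient_level, seed = seed),
            class = "physio_profile")
}

#' @export
print.physio_profile <- function(x, ...) {
  cat(sprintf(
    "<physio_profile> SpO2 %.1f%%  HR %.0f bpm  PI %.2f%%  DC(red/ir) %.3g/%.3g  noise %.3g\n",
    x$spo2, x$heart_rate, x$perfusion_index, x$dc_red, x$dc_ir, x$noise_sd))
  invisible(x)
}

# The four-slot LED cycle of the acquisition front end.
SLOT_CYCLE <- c("RED_ON", "BOTH_OFF", "IR_ON", "BOTH_OFF")

# Canonical one-beat pulse waveform on cardiac phase [0, 1): fundamental
# plus a phase-shifted second harmonic, giving a single systolic peak per
# beat with a faster upstroke than decay (rise occupies ~43% of the cycle).
# Deliberately gentle in harmonic content (nothing above twice the heart
# rate, so well below the 10 Hz noise filter for all valid profiles): the
# causal high-pass in the AC path phase-rotates low beat harmonics, and a
# peakier waveform would have its peak-to-peak amplitude visibly distorted
# by that skew. Returned centred (zero mean over a cycle) and scaled to
# unit peak-to-peak amplitude, so multiplying by an amplitude gives an AC
# waveform with exactly that peak-to-peak excursion.
pulse_waveform <- function(phase) {
  shape <- function(p) sin(2 * pi * p) + 0.15 * sin(4 * pi * p + pi / 4)
  grid <- seq(0, 1, length.out = 2048L)[-2048L]
  g <- shape(grid)
  (shape(phase %% 1) - mean(g)) / (max(g) - min(g))
}

# Cardiac phase of the systolic peak of the canonical waveform.
pulse_peak_phase <- function() {
  grid <- seq(0, 1, length.out = 2048L)[-2048L]
  grid[which.max(pulse_waveform(grid))]
}

# Phase offset placing the first systolic peak ~0.18 s after stream start:
# late enough that the first beat clears the filter-chain start-up
# transient, early enough that at the default 75 bpm the second beat also
# falls inside the first second (so the very first per-second record can
# already count two beats).
pulse_phase0 <- function(heart_rate) {
  (pulse_peak_phase() - 0.18 * heart_rate / 60) %% 1
}

# Internal synthesis core shared by synthesize_stream() and the closed-loop
# driver: emits `n_cycles` four-slot frames at the given true SpO2 (a vector,
# one value per cycle), advancing the cardiac phase, drawing noise from the
# ambient RNG.  `valid` marks finger-present cycles; invalid cycles collapse
# to ambient light only.
synth_state_init <- function(profile, sample_rate) {
  if (sample_rate <= 0 || sample_rate %% 4 != 0)
    stop("`sample_rate` must be a positive multiple of 4 (one sample per LED slot)",
         call. = FALSE)
  list(profile = profile, fs = sample_rate, fs_cycle = sample_rate / 4,
       phase = pulse_phase0(profile$heart_rate), t = 0)
}

synth_emit <- function(state, n_cycles, spo2, valid = TRUE) {
  pr <- state$profile
  fs_cyc <- state$fs_cycle
  spo2 <- rep_len(spo2, n_cycles)
  valid <- rep_len(valid, n_cycles)

  phase <- state$phase + (seq_len(n_cycles) - 1) * pr$heart_rate / 60 / fs_cyc
  p <- pulse_waveform(phase)

  r_target <- (110 - spo2) / 25            # ratio-of-ratios to embed
  amp_ir <- pr$perfusion_index / 100 * pr$dc_ir
  amp_red <- r_target * pr$perfusion_index / 100 * pr$dc_red

  base <- matrix(pr$ambient_level, nrow = 4, ncol = n_cycles)
  ac <- matrix(0, nrow = 4, ncol = n_cycles)
  on <- valid
  base[1, on] <- base[1, on] + pr$dc_red
  base[3, on] <- base[3, on] + pr$dc_ir
  ac[1, on] <- amp_red[on] * p[on]
  ac[3, on] <- amp_ir * p[on]

  noise <- matrix(stats::rnorm(4 * n_cycles, 0, pr$noise_sd), nrow = 4)
  state$phase <- (state$phase + n_cycles * pr$heart_rate / 60 / fs_cyc) %% 1
  state$t <- state$t + n_cycles / fs_cyc
  list(base = as.numeric(base), ac = as.numeric(ac),
       noise = as.numeric(noise),
       slot = rep(SLOT_CYCLE, n_cycles),
       valid = rep(valid, each = 4), state = state)
}

#' Synthesize a multiplexed two-wavelength PPG stream
#'
#' Generates the raw photodiode sample stream an acquisition front end would
#' capture: a four-slot LED cycle (red on, both off, infra-red on, both off)
#' repeated at `sample_rate` samples per second, carrying a pulsatile
#' waveform whose embedded ratio-of-ratios R equals `(110 - spo2) / 25`, so
#' the downstream calibration `SpO2 = 110 - 25 R` is exactly invertible.
#' Both-off slots carry ambient light plus noise only.
#'
#' @param profile A [physio_profile()].
#' @param duration Stream length in seconds (> 0; need not be whole).
#' @param sample_rate Acquisition rate in samples per second; must be a
#'   positive multiple of 4. Default 500, giving 125 samples/s per channel.
#' @param schedule Optional data frame with columns `t` (seconds) and `spo2`
#'   giving a piecewise-constant true-saturation trajectory; the profile's
#'   `spo2` applies before the first scheduled time.
#' @return An object of class `ppg_stream`: the sample vector, per-sample
#'   slot labels, the per-second ground-truth trajectory, and the generating
#'   profile.
#' @examples
#' s <- synthesize_stream(physio_profile(seed = 1), duration = 2)
#' length(s$samples)  # 2 s x 500 samples/s
#' @export
synthesize_stream <- function(profile, duration, sample_rate = 500,
                              schedule = NULL) {
  stopifnot(inherits(profile, "physio_profile"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  if (!is.null(schedule)) {
    if (!is.data.frame(schedule) || !all(c("t", "spo2") %in% names(schedule)))
      stop("`schedule` must be a data frame with columns `t` and `spo2`",
           call. = FALSE)
    schedule <- schedule[order(schedule$t), , drop = FALSE]
  }

  st <- synth_state_init(profile, sample_rate)
  n_cycles <- floor(duration * st$fs_cycle)
  t_cyc <- (seq_len(n_cycles) - 1) / st$fs_cycle
  spo2_cyc <- rep(profile$spo2, n_cycles)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    idx <- findInterval(t_cyc, schedule$t)
    spo2_cyc[idx > 0] <- schedule$spo2[idx[idx > 0]]
  }

  em <- with_seed(profile$seed, synth_emit(st, n_cycles, spo2_cyc))

  n_sec <- floor(duration)
  t_sec <- seq_len(n_sec) - 1
  sec_idx <- pmin(floor(t_sec * st$fs_cycle) + 1, n_cycles)
  truth <- data.frame(t = t_sec,
                      spo2 = spo2_cyc[sec_idx],
                      heart_rate = rep(profile$heart_rate, n_sec),
                      perfusion_index = rep(profile$perfusion_index, n_sec),
                      valid = rep(TRUE, n_sec))

  structure(list(sample_rate = sample_rate,
                 samples = em$base + em$ac + em$noise,
                 slot = em$slot,
                 sample_valid = em$valid,
                 components = list(base = em$base, ac = em$ac,
                                   noise = em$noise,
                                   artifact = numeric(length(em$base))),
                 truth = truth,
                 profile = profile,
                 duration = duration),
            class = "ppg_stream")
}

#' @export
print.ppg_stream <- function(x, ...) {
  cat(sprintf("<ppg_stream> %.6g s at %d samples/s (%d samples), %d truth records\n",
              x$duration, x$sample_rate, length(x$samples), nrow(x$truth)))
  invisible(x)
}

#' Inject artifacts into a synthesized stream
#'
#' Overlays typed disturbance events on a clean stream: `no_finger` intervals
#' (pulsatile component vanishes and the detector collapses to ambient light,
#' with the ground truth marked invalid), `motion` bursts (an additive
#' sinusoidal interference tone, e.g. 50 Hz mains-like), and linear baseline
#' `drift`. Samples outside every event are unchanged.
#'
#' @param stream A `ppg_stream`.
#' @param artifacts A list of events, each a list with `type` (one of
#'   `"no_finger"`, `"motion"`, `"drift"`), `start` and `end` times in
#'   seconds (half-open interval `[start, end)`), plus `amplitude` and `freq`
#'   (Hz, default 50) for `motion`, and `slope` (units/s) for `drift`.
#' @return A modified `ppg_stream`.
#' @examples
#' s <- synthesize_stream(physio_profile(seed = 1), duration = 10)
#' s2 <- inject_artifacts(s, list(list(type = "no_finger", start = 5, end = 8)))
#' truth_series(s2)$valid
#' @export
inject_artifacts <- function(stream, artifacts) {
  stopifnot(inherits(stream, "ppg_stream"))
  if (length(artifacts) == 0) return(stream)
  types <- vapply(artifacts, function(a) a$type, character(1))
  if (!all(types %in% c("no_finger", "motion", "drift")))
    stop("unknown artifact type; use no_finger, motion or drift", call. = FALSE)
  for (ty in unique(types)) {
    ev <- artifacts[types == ty]
    iv <- t(vapply(ev, function(a) c(a$start, a$end), numeric(2)))
    if (any(iv[, 2] <= iv[, 1]))
      stop("artifact intervals must satisfy start < end", call. = FALSE)
    o <- order(iv[, 1])
    if (nrow(iv) > 1 && any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
      stop(sprintf("overlapping `%s` intervals", ty), call. = FALSE)
  }

  t_samp <- (seq_along(stream$samples) - 1) / stream$sample_rate
  cm <- stream$components
  pr <- stream$profile
  for (a in artifacts) {
    in_ev <- t_samp >= a$start & t_samp < a$end
    if (!any(in_ev)) next
    if (a$type == "no_finger") {
      cm$ac[in_ev] <- 0
      cm$base[in_ev] <- pr$ambient_level
      stream$sample_valid[in_ev] <- FALSE
      sec_hit <- stream$truth$t < a$end & (stream$truth$t + 1) > a$start
      stream$truth$valid[sec_hit] <- FALSE
    } else if (a$type == "motion") {
      f <- if (is.null(a$freq)) 50 else a$freq
      cm$artifact[in_ev] <- cm$artifact[in_ev] +
        a$amplitude * sin(2 * pi * f * (t_samp[in_ev] - a$start))
    } else { # drift
      cm$artifact[in_ev] <- cm$artifact[in_ev] +
        a$slope * (t_samp[in_ev] - a$start)
    }
  }
  stream$components <- cm
  stream$samples <- cm$base + cm$ac + cm$noise + cm$artifact
  stream
}

#' Per-second ground-truth vitals of a synthesized stream
#'
#' @param stream A `ppg_stream`.
#' @return A data frame with one row per whole second: `t`, `spo2`,
#'   `heart_rate`, `perfusion_index`, `valid`. Truth is emitted on
#'   whole-second boundaries, covering the half-open interval `[t, t+1)`.
#' @export
truth_series <- function(stream) {
  stopifnot(inherits(stream, "ppg_stream"))
  stream$truth
}

#' Write / read a multiplexed stream as CSV
#'
#' Columns: `index` (1-based sample index), `time_s`, `slot_label`, `value`.
#' Values are printed with 17 significant digits so a round trip is exact.
#'
#' @param stream A `ppg_stream`.
#' @param path File path.
#' @return `write_stream_csv` returns `path` invisibly; `read_stream_csv`
#'   returns a `ppg_stream` (without ground truth, which is not serialized).
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "ppg_stream"))
  lines <- c("index,time_s,slot_label,value",
             sprintf("%d,%.17g,%s,%.17g",
                     seq_along(stream$samples),
                     (seq_along(stream$samples) - 1) / stream$sample_rate,
                     stream$slot, stream$samples))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stream_csv
#' @param sample_rate Acquisition rate of the serialized stream.
#' @export
read_stream_csv <- function(path, sample_rate = 500) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric",
                                             "character", "numeric"))
  need <- c("index", "time_s", "slot_label", "value")
  if (!all(need %in% names(df)))
    stop("stream CSV must have columns index, time_s, slot_label, value",
         call. = FALSE)
  structure(list(sample_rate = sample_rate, samples = df$value,
                 slot = df$slot_label,
                 sample_valid = rep(TRUE, nrow(df)),
                 components = NULL, truth = NULL, profile = NULL,
                 duration = nrow(df) / sample_rate),
            class = "ppg_stream")
}
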