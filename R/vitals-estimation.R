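#' Ratio-of-ratios of the two PPG channels
#'
#' R = (AC_red / DC_red) / (AC_ir / DC_ir), the normalized red-to-infra-red
#' pulsatile contrast that the empirical calibration maps to SpO2.
#'
#' @param ac_red,dc_red,ac_ir,dc_ir Window-aggregate AC (peak-to-peak) and DC
#'   amplitudes of the red and infra-red channels; all must be positive.
#' @return R, dimensionless.
#' @examples
#' compute_ratio(0.02, 2, 0.02, 2)  # 1
#' @export
compute_ratio <- function(ac_red, dc_red, ac_ir, dc_ir) {
  vals <- c(ac_red = ac_red, dc_red = dc_red, ac_ir = ac_ir, dc_ir = dc_ir)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid measurement: AC and DC amplitudes must all be positive",
         call. = FALSE)
  (ac_red / dc_red) / (ac_ir / dc_ir)
}

#' Empirical SpO2 calibration
#'
#' Maps the ratio-of-ratios to oxygen saturation with the empirical line
#' SpO2 = 110 - 25 R, clamped to \[0, 100\] (saturation is a percentage of
#' total haemoglobin, so the raw line's values above 100 for R < 0.4 are
#' clipped). Strictly decreasing in R before clamping.
#'
#' @param r Ratio-of-ratios, non-negative (vectorized).
#' @return SpO2 in percent.
#' @examples
#' spo2_from_ratio(c(0.5, 1, 1.6))  # 97.5 85 70
#' @export
spo2_from_ratio <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("ratio must be non-negative", call. = FALSE)
  pmin(100, pmax(0, 110 - 25 * r))
}

#' Detect systolic peaks in a pulsatile (AC) series
#'
#' A sample is a systolic peak when it is a local maximum, exceeds an
#' amplitude threshold, and is the maximum of its +/- one-refractory-interval
#' neighbourhood (which rejects small noise bumps riding on the beat's
#' slopes); a refractory interval is then enforced in time order (a
#' candidate within the refractory window of the last kept peak is dropped),
#' matching the 4 Hz ceiling of the PPG band. Deterministic; a flat series
#' yields zero peaks.
#'
#' @param ac Numeric AC series.
#' @param fs Sampling rate, samples/s.
#' @param refractory Minimum peak spacing in seconds (default 0.25 s).
#' @param peak_frac Threshold as a fraction of the maximum positive
#'   excursion (default 0.3).
#' @return Integer vector of peak indices (possibly empty).
#' @export
detect_pulses <- function(ac, fs, refractory = 0.25, peak_frac = 0.3) {
  n <- length(ac)
  if (n < 3) return(integer(0))
  mx <- max(ac)
  if (!is.finite(mx) || mx <= 0 || diff(range(ac)) == 0) return(integer(0))
  thr <- peak_frac * mx
  core <- ac[2:(n - 1)]
  cand <- which(core > ac[1:(n - 2)] & core >= ac[3:n] & core > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  gap <- max(1, round(refractory * fs))
  dom <- vapply(cand, function(i) {
    ac[i] >= max(ac[max(1, i - gap):min(n, i + gap)])
  }, logical(1))
  cand <- cand[dom]
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1]
  last <- cand[1]
  for (i in cand[-1]) {
    if (i - last >= gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Heart rate from pulse and sample counts
#'
#' HR (bpm) = fs x 60 / (average number of samples per heart pulse), where
#' the average is `n_samples / n_pulses` over the analysis window.
#'
#' @param fs Sampling rate, samples/s.
#' @param n_samples Number of samples spanned by the counted pulses.
#' @param n_pulses Number of heart pulses in that span. Zero pulses is not an
#'   error: it yields `NA` (a "no rate" signal; the caller invalidates the
#'   record).
#' @return Beats per minute, or `NA_real_` when no pulses were seen.
#' @examples
#' heart_rate(125, 100, 1)  # 75 bpm
#' @export
heart_rate <- function(fs, n_samples, n_pulses) {
  check_range(fs, "fs", 0, Inf, open_lo = TRUE)
  if (n_pulses < 1) return(NA_real_)
  if (n_samples < 1) stop("`n_samples` must be at least 1", call. = FALSE)
  fs * 60 / (n_samples / n_pulses)
}

#' Perfusion index
#'
#' PI = 100 x AC_ir / DC_ir, the pulsatile-to-baseline amplitude ratio of
#' the infra-red channel in percent.
#'
#' @param ac_ir Window-aggregate AC (peak-to-peak) amplitude, >= 0.
#' @param dc_ir Window-aggregate DC level, > 0.
#' @return Percent.
#' @export
perfusion_index <- function(ac_ir, dc_ir) {
  if (!is.finite(dc_ir) || dc_ir <= 0)
    stop("`dc_ir` must be positive", call. = FALSE)
  if (!is.finite(ac_ir) || ac_ir < 0)
    stop("`ac_ir` must be non-negative", call. = FALSE)
  100 * ac_ir / dc_ir
}

#' Weighted moving average over a value history
#'
#' Stabilizes per-second vitals: the most recent values are averaged with
#' positive weights normalized to one. A history shorter than the weight
#' vector uses the trailing (most-recent-aligned) weights, renormalized; the
#' output is always bounded by the window's min and max.
#'
#' @param history Numeric vector, oldest first; must be non-empty.
#' @param weights Positive weights, oldest first. Default `1:5`, a linear
#'   ramp over a 5-second window.
#' @return The smoothed value.
#' @examples
#' smooth_wma(c(90, 100), weights = c(1, 3))  # 97.5
#' @export
smooth_wma <- function(history, weights = 1:5) {
  if (length(history) == 0) stop("history must be non-empty", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  k <- min(length(history), length(weights))
  h <- utils::tail(history, k)
  w <- utils::tail(weights, k)
  sum(h * w) / sum(w)
}

#' Configuration of the per-second vitals estimator
#'
#' @param wma_weights Positive weights for the SpO2/HR stabilizing moving
#'   average, oldest first (default a 5 s linear ramp `1:5`).
#' @param hr_window Sliding analysis window in seconds for pulse counting
#'   (default 8 s: at least 4 beats at the 30 bpm lower bound).
#' @param dc_floor,pi_floor Signal-presence thresholds, as in
#'   [signal_present()].
#' @param refractory,peak_frac Pulse-detector parameters, as in
#'   [detect_pulses()].
#' @return A list of class `vitals_config`.
#' @export
vitals_config <- function(wma_weights = 1:5, hr_window = 8,
                          dc_floor = 0.1, pi_floor = 0.1,
                          refractory = 0.25, peak_frac = 0.3) {
  if (any(wma_weights <= 0)) stop("wma_weights must be positive", call. = FALSE)
  check_range(hr_window, "hr_window", 2, Inf)
  structure(list(wma_weights = wma_weights, hr_window = hr_window,
                 dc_floor = dc_floor, pi_floor = pi_floor,
                 refractory = refractory, peak_frac = peak_frac),
            class = "vitals_config")
}

# An empty (all-NA, invalid) vitals record.
invalid_record <- function(t) {
  data.frame(t = t, spo2 = NA_real_, heart_rate = NA_real_,
             perfusion_index = NA_real_, valid = FALSE, r_ratio = NA_real_)
}

# Invalidate a tick and restart the measurement: filter chains, analysis
# buffers and smoothing histories are dropped so that recovery after signal
# loss starts from a clean state instead of fighting the step transient the
# loss injected into the filters.
invalid_tick <- function(state, t) {
  state$red_chain <- NULL
  state$ir_chain <- NULL
  state$buf_ac_red <- numeric(0)
  state$buf_ac_ir <- numeric(0)
  state$buf_dc_red <- numeric(0)
  state$buf_dc_ir <- numeric(0)
  state$spo2_hist <- numeric(0)
  state$hr_hist <- numeric(0)
  list(record = invalid_record(t), state = state)
}

#' Initialize streaming vitals-estimation state
#'
#' @param fs_channel Per-channel sampling rate (125 at the default
#'   acquisition rate).
#' @param config A [vitals_config()].
#' @return Opaque state for [vitals_tick()].
#' @export
vitals_state_init <- function(fs_channel, config = vitals_config()) {
  stopifnot(inherits(config, "vitals_config"))
  list(fs = fs_channel, config = config,
       red_chain = NULL, ir_chain = NULL,
       buf_ac_red = numeric(0), buf_ac_ir = numeric(0),
       buf_dc_red = numeric(0), buf_dc_ir = numeric(0),
       spo2_hist = numeric(0), hr_hist = numeric(0))
}

#' Process one second of channel samples and emit one vitals record
#'
#' The streaming heart of the reader: pushes one second of ambient-corrected
#' red and infra-red samples through the filter cascade, updates the sliding
#' analysis window, detects beats on the infra-red AC trace, aggregates the
#' AC amplitude as the peak-to-peak excursion of the beat-ensemble average
#' (the beat anchors found on the infra-red trace are applied to both
#' channels) and the DC level as the window mean of the DC track, and emits
#' exactly one record for the second.
#' The record is invalid — carrying no vitals values — when the
#' signal-presence test fails, fewer than two beats are seen, or the raw
#' heart rate falls outside 30--240 bpm; invalid seconds do not update the
#' smoothing histories.
#'
#' @param state State from [vitals_state_init()] (or a previous tick).
#' @param red,ir One second of ambient-corrected channel samples each.
#' @param t Timestamp of the record (start of the second, so the record
#'   covers `[t, t+1)`).
#' @return A list with `record` (one-row data frame: `t`, `spo2`,
#'   `heart_rate`, `perfusion_index`, `valid`, `r_ratio`) and the updated
#'   `state`.
#' @export
vitals_tick <- function(state, red, ir, t) {
  cfg <- state$config
  fs <- state$fs
  if (is.null(state$red_chain)) {
    # initialize filter states at the mean of the first second: the mean is
    # the best instant DC estimate, and a steady state at the DC level lets
    # even the first beat through the AC path undistorted
    state$red_chain <- chain_init(fs, x0 = mean(red))
    state$ir_chain <- chain_init(fs, x0 = mean(ir))
  }
  pr <- chain_push(state$red_chain, red)
  pi_ <- chain_push(state$ir_chain, ir)
  state$red_chain <- pr$chain
  state$ir_chain <- pi_$chain

  wlen <- round(cfg$hr_window * fs)
  trim <- function(buf, new) utils::tail(c(buf, new), wlen)
  state$buf_ac_red <- trim(state$buf_ac_red, pr$ac)
  state$buf_ac_ir <- trim(state$buf_ac_ir, pi_$ac)
  state$buf_dc_red <- trim(state$buf_dc_red, pr$dc)
  state$buf_dc_ir <- trim(state$buf_dc_ir, pi_$dc)

  # signal presence over the most recent second
  # signal presence is judged on the current second alone: the mean of the
  # raw corrected infra-red samples is an instant DC estimate (the 0.1 Hz
  # DC track would take ~10 s to notice the finger leaving), and the AC
  # excursion over the second must clear the perfusion-index floor
  dc_ir_now <- mean(ir)
  ac_ir_win <- state$buf_ac_ir
  present <- is.finite(dc_ir_now) && dc_ir_now >= cfg$dc_floor &&
    100 * diff(range(utils::tail(ac_ir_win, fs))) / dc_ir_now >= cfg$pi_floor

  if (!present)
    return(invalid_tick(state, t))

  # too few beats is a lock-on condition, not signal loss: the record is
  # invalid but the analysis window keeps accumulating
  peaks <- detect_pulses(ac_ir_win, fs, cfg$refractory, cfg$peak_frac)
  if (length(peaks) < 2)
    return(list(record = invalid_record(t), state = state))

  # AC amplitude via beat-ensemble averaging: segments of one beat length,
  # anchored at the infra-red peaks, are averaged sample-wise (noise shrinks
  # with the number of beats) and the peak-to-peak of the mean beat is the
  # aggregate. The same beat anchors are applied to both channels, so any
  # filter-induced shape distortion cancels in the ratio-of-ratios.
  seg_len <- min(diff(peaks))
  if (seg_len < 3)
    return(list(record = invalid_record(t), state = state))
  anchors <- peaks[-length(peaks)]
  mean_beat <- function(x) {
    rowMeans(vapply(anchors, function(p0) x[p0:(p0 + seg_len - 1)],
                    numeric(seg_len)))
  }
  amp_ir <- diff(range(mean_beat(ac_ir_win)))
  dc_ir <- mean(state$buf_dc_ir)
  dc_red <- mean(state$buf_dc_red)

  # the ratio-of-ratios uses RMS amplitudes: phase-insensitive (immune to
  # the causal high-pass's waveform skew) and free of the peak-selection
  # noise bias; both channels carry the same beat shape, so the RMS ratio
  # equals the peak-to-peak ratio
  rms_ir <- sqrt(mean(ac_ir_win^2))
  rms_red <- sqrt(mean(state$buf_ac_red^2))

  hr_raw <- heart_rate(fs, peaks[length(peaks)] - peaks[1],
                       length(peaks) - 1)
  if (!is.finite(hr_raw) || hr_raw < 30 || hr_raw > 240 ||
      amp_ir <= 0 || rms_red <= 0 || dc_ir <= 0 || dc_red <= 0)
    return(list(record = invalid_record(t), state = state))

  r <- compute_ratio(rms_red, dc_red, rms_ir, dc_ir)
  spo2_raw <- spo2_from_ratio(r)
  pi_val <- perfusion_index(amp_ir, dc_ir)

  state$spo2_hist <- utils::tail(c(state$spo2_hist, spo2_raw),
                                 length(cfg$wma_weights))
  state$hr_hist <- utils::tail(c(state$hr_hist, hr_raw),
                               length(cfg$wma_weights))
  rec <- data.frame(t = t,
                    spo2 = smooth_wma(state$spo2_hist, cfg$wma_weights),
                    heart_rate = smooth_wma(state$hr_hist, cfg$wma_weights),
                    perfusion_index = pi_val,
                    valid = TRUE, r_ratio = r)
  list(record = rec, state = state)
}

#' Run the whole reader pipeline over a synthesized stream
#'
#' Demultiplexes, ambient-corrects, filters and estimates vitals second by
#' second, emitting one record per whole second of the stream (the per-second
#' cadence of the reader).
#'
#' @param stream A `ppg_stream`.
#' @param config A [vitals_config()].
#' @return A data frame of class `vitals_log` with one row per second:
#'   `t`, `spo2`, `heart_rate`, `perfusion_index`, `valid`, `r_ratio`.
#' @examples
#' s <- synthesize_stream(physio_profile(spo2 = 94, seed = 1), duration = 15)
#' v <- estimate_vitals(s)
#' tail(v$spo2, 3)
#' @export
estimate_vitals <- function(stream, config = vitals_config()) {
  bundle <- ambient_correct(demultiplex(stream))
  fs <- bundle$fs_channel
  n_sec <- floor(length(bundle$red) / fs)
  st <- vitals_state_init(fs, config)
  recs <- vector("list", n_sec)
  for (k in seq_len(n_sec)) {
    idx <- ((k - 1) * fs + 1):(k * fs)
    out <- vitals_tick(st, bundle$red[idx], bundle$infrared[idx], t = k - 1)
    st <- out$state
    recs[[k]] <- out$record
  }
  res <- do.call(rbind, recs)
  class(res) <- c("vitals_log", "data.frame")
  attr(res, "config") <- config
  res
}

#' @export
print.vitals_log <- function(x, ...) {
  v <- x$valid
  cat(sprintf("<vitals_log> %d records (%d valid)\n", nrow(x), sum(v)))
  if (any(v))
    cat(sprintf("  SpO2 %.1f-%.1f%%  HR %.0f-%.0f bpm  PI %.2f-%.2f%%\n",
                min(x$spo2[v]), max(x$spo2[v]),
                min(x$heart_rate[v]), max(x$heart_rate[v]),
                min(x$perfusion_index[v]), max(x$perfusion_index[v])))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more records\n", nrow(x) - 6))
  invisible(x)
}
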