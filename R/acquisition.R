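#' LED slot label for a sample index
#'
#' The acquisition front end drives the red / infra-red LED pair through the
#' repeating four-slot sequence ON/OFF, OFF/OFF, OFF/ON, OFF/OFF, one A/D
#' sample per slot. This returns the slot label for a 0-based sample index.
#'
#' @param cycle_index 0-based sample index (vectorized), non-negative.
#' @return Character vector of labels in `RED_ON`, `BOTH_OFF`, `IR_ON`.
#' @examples
#' led_slot(0:7)
#' @export
led_slot <- function(cycle_index) {
  if (!is.numeric(cycle_index) || any(cycle_index < 0) || any(is.na(cycle_index)))
    stop("`cycle_index` must be non-negative", call. = FALSE)
  SLOT_CYCLE[cycle_index %% 4 + 1]
}

#' Demultiplex a raw stream into per-channel sample series
#'
#' Splits the slot-multiplexed photodiode stream into the red PPG series,
#' the infra-red PPG series, and the both-off ambient reference series. At
#' the default 500 samples/s acquisition rate each PPG channel comes out at
#' 125 samples/s and the reference at 250 samples/s. A trailing partial
#' four-slot cycle is discarded.
#'
#' Streams must begin at a `RED_ON` slot. If `x` is a bare numeric vector
#' (no slot labels), the cycle phase is recovered by a resynchronization
#' scan: the phase whose would-be both-off slots have the lowest mean level
#' is taken as the ambient phase, and leading samples before the first full
#' cycle are dropped.
#'
#' @param x A `ppg_stream`, or a numeric vector of raw samples.
#' @param sample_rate Acquisition rate, used when `x` is a bare vector.
#' @return An object of class `channel_bundle` with fields `fs_channel`,
#'   `red`, `infrared`, `reference`, `t0` and `sample_rate`.
#' @examples
#' s <- synthesize_stream(physio_profile(seed = 1), duration = 1)
#' b <- demultiplex(s)
#' length(b$red)  # 125
#' @export
demultiplex <- function(x, sample_rate = 500) {
  if (inherits(x, "ppg_stream")) {
    samples <- x$samples
    slot <- x$slot
    sample_rate <- x$sample_rate
  } else if (is.numeric(x)) {
    samples <- as.numeric(x)
    slot <- NULL
  } else stop("`x` must be a ppg_stream or a numeric vector", call. = FALSE)

  t0 <- 0
  if (is.null(slot)) {
    ph <- resync_phase(samples)
    if (ph > 0) {
      drop <- 4 - ph
      samples <- samples[-seq_len(drop)]
      t0 <- drop / sample_rate
    }
    slot <- led_slot(seq_along(samples) - 1)
  }

  n_keep <- 4 * (length(samples) %/% 4)
  if (n_keep == 0) stop("stream shorter than one full LED cycle", call. = FALSE)
  samples <- samples[seq_len(n_keep)]
  slot <- slot[seq_len(n_keep)]
  expected <- rep(SLOT_CYCLE, n_keep / 4)
  if (!identical(slot, expected))
    stop("corrupted stream: slot labels do not follow the RED_ON, BOTH_OFF, IR_ON, BOTH_OFF cycle",
         call. = FALSE)

  structure(list(fs_channel = sample_rate / 4,
                 red = samples[seq(1, n_keep, by = 4)],
                 infrared = samples[seq(3, n_keep, by = 4)],
                 reference = samples[seq(2, n_keep, by = 2)],
                 t0 = t0, sample_rate = sample_rate,
                 ambient_corrected = FALSE),
            class = "channel_bundle")
}

# Cycle-phase recovery for an unlabeled stream. Ambient (both-off) slots are
# the darkest, which pins the phase down to parity only: the two LED-on slots
# cannot be told apart from levels alone (red and infra-red DC may be equal).
# Of the two parity-consistent phases we take the smaller offset, i.e. assume
# at most one leading partial cycle was clipped. Returns the slot offset of
# the first sample within the RED_ON-first cycle (0 or 1).
resync_phase <- function(samples) {
  n <- 4 * (length(samples) %/% 4)
  if (n < 8) return(0L)
  lvl <- rowMeans(matrix(samples[seq_len(n)], nrow = 4))
  if (lvl[2] + lvl[4] <= lvl[1] + lvl[3]) 0L else 1L
}

#' @export
print.channel_bundle <- function(x, ...) {
  cat(sprintf("<channel_bundle> %d samples/channel at %g samples/s%s\n",
              length(x$red), x$fs_channel,
              if (isTRUE(x$ambient_corrected)) " (ambient-corrected)" else ""))
  invisible(x)
}

#' Subtract ambient light from the PPG channels
#'
#' Each red / infra-red sample has the temporally nearest both-off reference
#' sample subtracted (ties broken toward the earlier reference), removing the
#' ambient-light pedestal common to all slots. The reference series is kept
#' for diagnostics.
#'
#' @param bundle A `channel_bundle`.
#' @return The bundle with corrected `red` and `infrared` and
#'   `ambient_corrected = TRUE`.
#' @export
ambient_correct <- function(bundle) {
  stopifnot(inherits(bundle, "channel_bundle"))
  n <- length(bundle$red)
  if (n == 0) return(bundle)
  cyc <- seq_len(n)
  # red sits in slot 1 of cycle c: nearest refs are slot 4 of cycle c-1 and
  # slot 2 of cycle c, both one sample away; tie -> earlier (previous cycle).
  idx_red <- ifelse(cyc == 1, 1L, 2L * (cyc - 1L))
  # infra-red sits in slot 3: slot 2 of the same cycle is one sample earlier.
  idx_ir <- 2L * cyc - 1L
  bundle$red <- bundle$red - bundle$reference[idx_red]
  bundle$infrared <- bundle$infrared - bundle$reference[idx_ir]
  bundle$ambient_corrected <- TRUE
  bundle
}

#' Decide whether a finger (a usable PPG signal) is present
#'
#' A window is declared signal-bearing when the ambient-corrected infra-red
#' DC level clears a floor AND the pulsatile (AC) excursion, extracted by the
#' filter cascade, is large enough relative to DC (a perfusion-index floor).
#' With both LEDs seeing only ambient light (no finger) the corrected DC
#' collapses to about zero and the test fails.
#'
#' @param bundle A `channel_bundle` spanning at least one second.
#' @param dc_floor Minimum corrected DC level (detector units). Default 0.1,
#'   i.e. 5\% of the generator's nominal infra-red DC of 2.0.
#' @param pi_floor Minimum perfusion index, percent. Default 0.1.
#' @return `TRUE` or `FALSE` (deterministic given the thresholds).
#' @export
signal_present <- function(bundle, dc_floor = 0.1, pi_floor = 0.1) {
  stopifnot(inherits(bundle, "channel_bundle"))
  if (length(bundle$infrared) < bundle$fs_channel)
    stop("window must span at least 1 s of channel samples", call. = FALSE)
  if (!isTRUE(bundle$ambient_corrected)) bundle <- ambient_correct(bundle)
  cp <- extract_components(bundle$infrared, bundle$fs_channel)
  dc_mean <- mean(cp$dc)
  if (!is.finite(dc_mean) || dc_mean < dc_floor) return(FALSE)
  pp <- diff(range(cp$ac))
  (100 * pp / dc_mean) >= pi_floor
}

#' Write a channel bundle as CSV
#'
#' Columns: `time_s`, `red`, `infrared`, `reference` (the reference runs at
#' twice the channel rate; the earlier of the two both-off samples of each
#' cycle is reported on the channel time base).
#'
#' @param bundle A `channel_bundle`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bundle_csv <- function(bundle, path) {
  stopifnot(inherits(bundle, "channel_bundle"))
  n <- length(bundle$red)
  t <- bundle$t0 + (seq_len(n) - 1) / bundle$fs_channel
  lines <- c("time_s,red,infrared,reference",
             sprintf("%.17g,%.17g,%.17g,%.17g", t, bundle$red,
                     bundle$infrared, bundle$reference[2 * seq_len(n) - 1]))
  writeLines(lines, path)
  invisible(path)
}
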