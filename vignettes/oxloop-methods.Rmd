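---
title: "Models and methods behind oxloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oxloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxloop)
```

`oxloop` simulates an automated oxygen administration system end to end: a
two-wavelength pulse oximeter (synthesis, acquisition, filtering,
estimation), a per-minute oxygen titration controller, and a virtual
patient that closes the loop. This vignette explains the models, the
tunable parameters, and the design decisions taken where the underlying
system description left the design open — with enough detail that a reader
can judge what passing tests do and do not demonstrate.

## The signal model

A transmissive probe shines red and infra-red LEDs through a fingertip in
the four-slot cycle ON/OFF, OFF/OFF, OFF/ON, OFF/OFF, one photodiode sample
per slot at 500 samples/s. Demultiplexing gives each PPG channel 125
samples/s and a 250 samples/s both-off ambient reference.

The generator (`synthesize_stream()`) works backwards from the quantities
the reader is supposed to recover. Each channel is

    x(t) = DC + amplitude * p(phase(t)) + ambient + noise,

where `p` is a canonical one-beat waveform on cardiac phase [0, 1),
centred to zero mean and scaled to unit peak-to-peak. The infra-red
amplitude is fixed by the perfusion index, `PI/100 * DC_ir`; the red
amplitude is then solved from the target ratio-of-ratios
`R = (110 - SpO2)/25`, which makes the empirical calibration
`SpO2 = 110 - 25R` exactly invertible. Both-off slots carry ambient light
plus noise only. Noise is additive white Gaussian on every slot
(`noise_sd`, default 0.005 on detector levels of 2.0 — a clean, well-
perfused recording); optional artifacts add a mains-like interference tone,
baseline drift, or no-finger intervals in which the pulsatile term vanishes
and the detector collapses to ambient light.

**Pulse morphology.** The hardware description never defines the beat
shape, so the choice is ours. We use fundamental plus a phase-shifted
second harmonic, `sin(2*pi*u) + 0.15 sin(4*pi*u + pi/4)`: a single systolic
peak, a faster upstroke than decay (the rise occupies ~43% of the cycle),
and no spectral content above twice the heart rate. The gentleness is
deliberate. The AC path's causal 4th-order high-pass rotates the phases of
low beat harmonics; for a peaky waveform (we first tried a two-Gaussian
systolic/diastolic shape) that skew distorts the peak-to-peak amplitude by
~10%, which is a property of the mandated filter cascade, not of any
estimator. With the two-harmonic shape the peak-to-peak survives the
cascade to within ~2.3% across 50–120 bpm. What this means for realism:
results here do not certify performance on strongly peaked or dicrotic
waveforms, motion-corrupted signals, or varying heart rates — the generator
emulates a cooperative patient on a good probe.

The first beat's peak is placed ~0.18 s into the stream so that, at the
default 75 bpm, the first one-second record already contains two detectable
beats. At slower rates the first record or two are honestly invalid (two
beats simply have not happened yet).

## The filter cascade

Three streaming filters per channel, designed with `signal::butter()` /
`signal::fir1()` at the channel rate:

| stage | design | purpose |
|---|---|---|
| `DC_TRACK` | 2nd-order Butterworth low-pass, cutoff 0.1 Hz | baseline (DC) |
| `DC_REMOVE` | 4th-order Butterworth high-pass, stop 0.1 Hz / pass 0.5 Hz | AC path, baseline removal |
| `NOISE_LP` | 10th-order FIR (11 taps), Kaiser window beta 0.5, cutoff 10 Hz | AC path, noise removal |

Two interpretation points, both consequences of a specification that gives
edges but not half-power points:

* The high-pass is stated as stop 0.1 Hz / pass 0.5 Hz with no −3 dB
  point. We place the −3 dB cutoff at 0.4 Hz: the 0.5 Hz pass edge then
  keeps ~0.92 of its amplitude through the whole AC path while 0.1 Hz is
  attenuated by ~48 dB. Putting the −3 dB point at 0.5 Hz itself would
  attenuate the pass edge to 0.71, which contradicts what a pass edge
  means.
* The 11 FIR taps returned by the windowed design are renormalized to exact
  unity DC gain (the raw design's DC gain is 1.23). An 11-tap filter has a
  transition roughly as wide as `fs/N` ≈ 11 Hz, so its response already
  droops inside the nominal passband: ~0.99 at 1 Hz, ~0.95 at 2.5 Hz, 0.88
  at the 4 Hz top of the PPG band. That droop is intrinsic to the mandated
  tap count; the tests therefore assert gain ≥ 0.9 up to 3 Hz and ≥ 0.85
  at 4 Hz rather than pretending the band edge is untouched.

`apply_stream()` carries direct-form state across chunks, so chunked
filtering is bit-identical to one-shot filtering — the property that makes
a per-second streaming reader equivalent to offline processing. Filter
states are initialized at the steady state for the mean of the first
second of data (the best instant DC estimate available); this suppresses
the start-up transient that a cold start would produce on a signal whose
DC pedestal is ~50 times its AC amplitude, and lets even the first beat
through undistorted. `settle_samples` still reports the impulse-response
settling estimate (the 0.1 Hz stage is the slowest at ~18 s) for callers
that want a conservative warm-up margin.

## Per-second vitals estimation

Each second, `vitals_tick()` updates an 8-second sliding analysis window
(four beats even at the 30 bpm lower bound) and computes:

* **Signal presence** — judged on the current second alone: mean corrected
  infra-red level ≥ `dc_floor` (default 0.1, i.e. 5% of the nominal
  detector level) and an AC excursion clearing a perfusion floor
  (`pi_floor`, default 0.1%). Judging on the instant mean rather than the
  0.1 Hz DC track matters: the track takes ~10 s to notice a removed
  finger. Loss of presence invalidates the record, stops titration
  upstream, and resets the filter chains, buffers and smoothing histories,
  so re-locking after the finger returns starts clean instead of fighting
  the step transient the loss injected into the filters. Detection and
  re-lock each cost at most about a second.
* **Beats** — local maxima of the infra-red AC trace above 30% of the
  window maximum that are also maxima of their ±0.25 s neighbourhood (the
  refractory interval implied by the 4 Hz band ceiling); the neighbourhood
  condition rejects noise bumps riding on the slow slopes of a beat.
  Too few beats is a lock-on condition, not signal loss: the record is
  invalid but the window keeps accumulating.
* **Heart rate** — `fs * 60 / (samples per pulse)` with the span between
  first and last detected peak divided by the number of inter-peak
  intervals. Valid records must land in 30–240 bpm.
* **Amplitude aggregates** — the DC aggregate is the window mean of the DC
  track. For the perfusion index (defined peak-to-peak) the AC aggregate
  is the peak-to-peak of the beat-ensemble average: one-beat segments
  anchored at the detected peaks, averaged sample-wise, so uncorrelated
  noise shrinks with the number of beats. For the ratio-of-ratios we use
  RMS amplitudes over the window instead. Two reasons: RMS is phase-
  insensitive (immune to the high-pass skew, which affects both channels
  identically anyway), and — decisive in practice — peak-anchored
  estimates inherit a selection bias under noise (anchors are chosen where
  noise pushes the infra-red trace up, and filter-correlated noise spreads
  that bias across neighbouring lags), which we measured as a systematic
  +2 SpO2 points at default noise. Both channels carry the same beat
  shape, so the RMS ratio equals the peak-to-peak ratio exactly in the
  noise-free limit.
* **Calibration** — `SpO2 = 110 - 25R`, clamped to [0, 100] because
  saturation is a percentage of total haemoglobin (the raw line exceeds
  100 for R < 0.4). The clamp is the only place the definitional
  oxyhaemoglobin fraction enters; we do not model haemoglobin species.
* **Stabilization** — a weighted moving average with linearly increasing
  weights over the last 5 valid seconds (`1:5`), applied to SpO2 and heart
  rate after calibration, not to R before it: smoothing the displayed and
  controlled quantity keeps the calibration exactly invertible per second
  and makes the smoothing window's meaning ("seconds of saturation
  history") transparent. The perfusion index is reported unsmoothed.

Under these defaults, noise-free recovery across SpO2 ∈ {80…98} and
HR ∈ {50, 75, 120} is exact to well under 1 saturation point and 2 bpm;
with default noise the SpO2 error stays within about half a point.

## The delivery controller

The controller consumes one record per second. Its behaviour is a direct
transcription of the delivery subsystem's rules:

* invalid record → display "Please Insert Your Finger", close the valve
  immediately (`no_signal_stop`);
* valid record → display SpO2/HR/PI; at most once every 60 s, titrate:
  below 94% add one step (default 0.5 L/min), above 98% remove one step,
  inside the band hold — always clipped to [0, 15] L/min;
* no record for more than 60 s → watchdog restart: valve closed, one
  restart per stall episode;
* flow maps to valve drive voltage affinely, 10 V at 15 L/min.

After any stop the flow restarts from zero rather than restoring its
previous value — the conservative safe state, since the controller cannot
know how long the signal was untrustworthy. The titration law is
deliberately the simplest rule consistent with a 94–98% target band;
illness-specific bands and full prescription tables are out of scope, and
the step size, band, period and limits are all configuration keys. A
hold-type band controller settles wherever in the band the ratchet first
stops rising, typically the lower half; it does not seek the band centre.

## The virtual patient

A first-order dose-response model: flow F sets a saturation setpoint
`s*(F) = min(100, baseline + gain * F)`, and the true saturation relaxes
toward it as `s <- s* + (s - s*) exp(-dt/tau)` — the exact solution of the
linear dynamics, so the trajectory is independent of the stepping scheme —
plus Gaussian jitter with standard deviation `noise_sd * sqrt(dt)`,
clamped to [0, 100]. The reference hypoxaemic patient used in the
closed-loop runs is baseline 85%, gain 2% per L/min, tau 45 s, jitter
0.3%/√s (stationary spread ≈ 1.4 saturation points at tau 45 s). The
model is monotone in flow by construction and makes no claim to gas-
exchange realism: no oxyhaemoglobin dissociation curve, no CO2 dynamics,
no illness-specific response shapes.

The oxygen bookkeeping helpers implement the standard content and delivery
relations `CaO2 = k1*Hb*SaO2 + k2*PaO2` (k1 = 1.34 ml/g, k2 = 0.023
ml·l⁻¹·kPa⁻¹, both configurable) and `DO2 = CO * CaO2`; they are not part
of the control law.

## The closed loop and its reproducibility

`run_closed_loop()` advances a discrete 1 s clock: patient → one second of
synthesized multiplexed samples at the current true saturation →
demultiplex and ambient-correct → vitals tick → transport → controller →
patient step under the commanded flow. The transport link is lossless by
default (drop probability and latency are opt-in). A single session seed
drives every random draw in sequence, so a session is reproducible byte
for byte in its logs; CSV and JSONL serializers print numbers with 17
significant digits specifically so that write/read round trips are exact.

In a 20-minute run with the reference patient, the flow ratchets up from
zero (the first titration happens at t = 60 s), the true saturation
crosses into the 94–98% band after roughly ten minutes, and the final five
minutes average about 94–97% depending on the seed — the jitter's ±1.4
spread means single seconds, and occasionally a whole window at the band's
lower edge, can graze 94%.

## Numerical and degenerate-input choices

* Ambient subtraction uses the temporally nearest both-off sample, ties
  resolved toward the earlier one; the first cycle's red sample, which has
  no earlier reference, uses its own cycle's.
* Unlabeled streams are re-aligned by scanning for the darkest slot
  parity; red and infra-red slots cannot be told apart from levels alone
  (their DC levels may be equal), so of the two parity-consistent phases
  the smaller offset is taken — the assumption that at most one partial
  cycle was clipped.
* A trailing partial LED cycle is discarded; a stream shorter than one
  full cycle is an error.
* Flat or all-zero AC input yields zero detected pulses (not an error);
  zero pulses yields "no rate" and an invalid record.
* Identical peak candidates within one refractory interval resolve to the
  earlier peak.
* Session durations are handled per whole second; fractional trailing
  seconds contribute samples but no record.

## Problem sizes in the tests

The suite synthesizes everything it needs at run time: unit streams of
1–30 s, a 15-point noise-free recovery grid at 16 s per cell, 120 s cadence
runs, and 20-minute closed-loop sessions (a 1200 s session simulates and
processes 600,000 multiplexed samples in a few seconds of wall time). These
sizes were chosen to exercise every settling time in the system — the
slowest being the 0.1 Hz DC track and the 45 s patient time constant — with
comfortable margin.

## Known limitations

* The calibration line is the published empirical one; no clinical
  recalibration is modelled, and accuracy claims transfer to real probes
  only after such calibration.
* Constant heart rate and perfusion within a session; no arrhythmia, no
  respiratory modulation, no motion-robust estimation.
* The ambient reference is subtracted, which is one reading of a reference
  channel whose use the source system leaves unstated.
* The watchdog models the delivery side only; reader-side hangs are
  represented through transport loss.
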