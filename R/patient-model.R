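#' Arterial oxygen content
#'
#' CaO2 = k1 x Hb x SaO2 + k2 x PaO2: haemoglobin-bound oxygen plus
#' dissolved oxygen. Default constants are the standard physiological
#' values: k1 = 1.34 ml of oxygen per gram of fully saturated haemoglobin
#' (Huefner's number), k2 = 0.023 ml of dissolved oxygen per litre of blood
#' per kPa of arterial oxygen tension.
#'
#' @param hb Haemoglobin concentration, g/l (>= 0).
#' @param sao2 Arterial haemoglobin saturation as a fraction in \[0, 1\].
#' @param pao2 Arterial oxygen partial pressure, kPa (>= 0).
#' @param k1 ml O2 bound per g of saturated Hb (default 1.34).
#' @param k2 ml O2 dissolved per l per kPa (default 0.023).
#' @return Oxygen content in ml O2 per litre of blood.
#' @examples
#' oxygen_content(150, 0.97, 13)  # about 195.3 ml/l
#' @export
oxygen_content <- function(hb, sao2, pao2, k1 = 1.34, k2 = 0.023) {
  check_range(hb, "hb", 0, Inf)
  check_range(sao2, "sao2", 0, 1)
  check_range(pao2, "pao2", 0, Inf)
  k1 * hb * sao2 + k2 * pao2
}

#' Global oxygen delivery
#'
#' DO2 = cardiac output x arterial oxygen content.
#'
#' @param co Cardiac output, l/min (>= 0).
#' @param cao2 Arterial oxygen content, ml/l (>= 0).
#' @return Oxygen delivery in ml O2 per minute.
#' @examples
#' oxygen_delivery(5, 200)  # 1000 ml/min
#' @export
oxygen_delivery <- function(co, cao2) {
  check_range(co, "co", 0, Inf)
  check_range(cao2, "cao2", 0, Inf)
  co * cao2
}

#' Virtual hypoxaemic patient
#'
#' A minimal dose-response model closing the control loop: supplemental
#' oxygen flow sets a saturation setpoint
#' `min(spo2_max, baseline_spo2 + gain * flow)`, and the true saturation
#' relaxes toward it with first-order dynamics of time constant `tau`, plus
#' optional Gaussian jitter. The defaults are the reference hypoxaemic
#' patient used throughout the package's simulations: untreated baseline
#' 85\%, gain 2\% per L/min, tau 45 s, jitter SD 0.3\%.
#'
#' @param baseline_spo2 Untreated saturation, percent.
#' @param gain Saturation gained per L/min of supplemental flow, percent.
#' @param tau First-order time constant, seconds (> 0).
#' @param spo2_max Saturation ceiling, percent (default 100).
#' @param hb Haemoglobin, g/l (for [oxygen_content()] bookkeeping).
#' @param cardiac_output Cardiac output, l/min.
#' @param pao2 Arterial oxygen tension, kPa.
#' @param noise_sd Jitter SD per sqrt(second), percent (0 disables).
#' @param seed Optional seed giving the patient its own reproducible noise
#'   stream, independent of the caller's RNG.
#' @return An object of class `patient_state` with `true_spo2` initialized
#'   at the baseline.
#' @examples
#' p <- patient_state(noise_sd = 0)
#' p <- step_patient(p, flow = 5, dt = 300)
#' p$true_spo2  # near 95: baseline 85 + 2 * 5
#' @export
patient_state <- function(baseline_spo2 = 85, gain = 2, tau = 45,
                          spo2_max = 100, hb = 150, cardiac_output = 5,
                          pao2 = 8, noise_sd = 0.3, seed = NULL) {
  check_range(baseline_spo2, "baseline_spo2", 0, 100, open_lo = TRUE)
  check_range(gain, "gain", 0, Inf)
  check_range(tau, "tau", 0, Inf, open_lo = TRUE)
  check_range(spo2_max, "spo2_max", baseline_spo2, 100)
  check_range(hb, "hb", 0, Inf)
  check_range(cardiac_output, "cardiac_output", 0, Inf)
  check_range(pao2, "pao2", 0, Inf)
  check_range(noise_sd, "noise_sd", 0, Inf)
  structure(list(true_spo2 = baseline_spo2, baseline_spo2 = baseline_spo2,
                 gain = gain, tau = tau, spo2_max = spo2_max,
                 hb = hb, cardiac_output = cardiac_output, pao2 = pao2,
                 noise_sd = noise_sd, seed = seed, rng_state = NULL),
            class = "patient_state")
}

#' @export
print.patient_state <- function(x, ...) {
  cat(sprintf(
    "<patient_state> SpO2 %.1f%% (baseline %.1f%%, gain %g %%/(L/min), tau %g s)\n",
    x$true_spo2, x$baseline_spo2, x$gain, x$tau))
  invisible(x)
}

# Draw n jitter values from the patient's private RNG stream (seeded) or the
# ambient RNG (seed NULL), without disturbing the caller's stream in the
# seeded case.
patient_jitter <- function(patient, n, sd) {
  if (is.null(patient$seed)) {
    return(list(x = stats::rnorm(n, 0, sd), patient = patient))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(patient$rng_state)) set.seed(as.integer(patient$seed))
  else assign(".Random.seed", patient$rng_state, envir = globalenv())
  x <- stats::rnorm(n, 0, sd)
  patient$rng_state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  list(x = x, patient = patient)
}

#' Advance the virtual patient by one time step
#'
#' Exact-exponential update of the first-order dynamics (no Euler drift):
#' `s <- s* + (s - s*) exp(-dt / tau)` with
#' `s* = min(spo2_max, baseline_spo2 + gain * flow)`, plus Gaussian jitter
#' with standard deviation `noise_sd * sqrt(dt)`, clamped to \[0, 100\].
#'
#' @param patient A `patient_state`.
#' @param flow Supplemental oxygen flow during the step, L/min (>= 0).
#' @param dt Step length, seconds (> 0).
#' @return The updated `patient_state`.
#' @export
step_patient <- function(patient, flow, dt) {
  stopifnot(inherits(patient, "patient_state"))
  check_range(flow, "flow", 0, Inf)
  check_range(dt, "dt", 0, Inf, open_lo = TRUE)
  setpoint <- min(patient$spo2_max, patient$baseline_spo2 + patient$gain * flow)
  s <- setpoint + (patient$true_spo2 - setpoint) * exp(-dt / patient$tau)
  if (patient$noise_sd > 0) {
    j <- patient_jitter(patient, 1, patient$noise_sd * sqrt(dt))
    patient <- j$patient
    s <- s + j$x
  }
  patient$true_spo2 <- min(100, max(0, s))
  patient
}
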