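#' Transport link between the reader and the delivery controller
#'
#' Abstracts the wireless link carrying one vitals record per second:
#' messages are delivered after a fixed latency with probability
#' `1 - drop_prob`. Drops feed the controller's staleness / watchdog path.
#'
#' @param drop_prob Per-message drop probability in \[0, 1\] (default 0:
#'   lossless, matching the nominal link).
#' @param latency Fixed delivery latency, seconds (default 0).
#' @return An object of class `transport_link` with delivery counters.
#' @export
transport_link <- function(drop_prob = 0, latency = 0) {
  check_range(drop_prob, "drop_prob", 0, 1)
  check_range(latency, "latency", 0, Inf)
  structure(list(drop_prob = drop_prob, latency = latency,
                 delivered = 0L, dropped = 0L),
            class = "transport_link")
}

#' Offer one record to the transport link
#'
#' @param link A `transport_link`.
#' @param record A one-row vitals record.
#' @return A list with the updated `link`, `delivered` (logical), and
#'   `record` (the delivered record with its timestamp advanced by the link
#'   latency, or `NULL` on a drop). Randomness comes from the ambient RNG,
#'   so a seeded session reproduces drop patterns exactly.
#' @export
transmit <- function(link, record) {
  stopifnot(inherits(link, "transport_link"))
  ok <- if (link$drop_prob <= 0) TRUE
        else if (link$drop_prob >= 1) FALSE
        else stats::runif(1) >= link$drop_prob
  if (ok) {
    link$delivered <- link$delivered + 1L
    record$t <- record$t + link$latency
    list(link = link, delivered = TRUE, record = record)
  } else {
    link$dropped <- link$dropped + 1L
    list(link = link, delivered = FALSE, record = NULL)
  }
}

#' Closed-loop session configuration
#'
#' Bundles every tunable of a simulated session: the sensor-side profile
#' (heart rate, perfusion, detector levels, noise), the virtual patient, the
#' controller, and the transport link. The profile's `spo2` field is ignored
#' in closed loop — the patient's true saturation drives synthesis each
#' second.
#'
#' @param duration Session length, seconds (default 1200 = 20 min).
#' @param sample_rate Acquisition rate, samples/s (default 500).
#' @param profile A [physio_profile()] (its `seed` should be `NULL`; the
#'   session seed governs all randomness).
#' @param patient A [patient_state()].
#' @param controller A [controller_state()].
#' @param transport A [transport_link()].
#' @param vitals A [vitals_config()].
#' @param no_finger Optional list of `c(start, end)` intervals (seconds)
#'   during which the finger is absent from the sensor.
#' @param seed Integer seed; together with the config it fully determines
#'   every output.
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration = 1200, sample_rate = 500,
                           profile = physio_profile(),
                           patient = patient_state(),
                           controller = controller_state(),
                           transport = transport_link(),
                           vitals = vitals_config(),
                           no_finger = NULL, seed = 1) {
  check_range(duration, "duration", 1, Inf)
  if (sample_rate <= 0 || sample_rate %% 4 != 0)
    stop("`sample_rate` must be a positive multiple of 4", call. = FALSE)
  stopifnot(inherits(profile, "physio_profile"),
            inherits(patient, "patient_state"),
            inherits(controller, "controller_state"),
            inherits(transport, "transport_link"),
            inherits(vitals, "vitals_config"))
  check_range(seed, "seed", -2^31, 2^31)
  if (!is.null(no_finger)) {
    stopifnot(is.list(no_finger),
              all(vapply(no_finger, length, integer(1)) == 2))
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 profile = profile, patient = patient,
                 controller = controller, transport = transport,
                 vitals = vitals, no_finger = no_finger, seed = seed),
            class = "session_config")
}

#' Read a session configuration from a YAML file
#'
#' Recognized top-level keys: `duration`, `sample_rate`, `seed`, and nested
#' blocks `profile`, `patient`, `controller`, `transport` whose entries are
#' passed to the matching constructors ([physio_profile()],
#' [patient_state()], [controller_state()], [transport_link()]). Unknown
#' keys raise a configuration error; omitted keys take the documented
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("duration", "sample_rate", "seed", "profile", "patient",
             "controller", "transport")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  build <- function(block, fn) {
    args <- raw[[block]]
    if (is.null(args)) return(fn())
    if (block == "controller" && !is.null(args$band))
      args$band <- as.numeric(unlist(args$band))
    do.call(fn, args)
  }
  args <- list(profile = build("profile", physio_profile),
               patient = build("patient", patient_state),
               controller = build("controller", controller_state),
               transport = build("transport", transport_link))
  for (k in c("duration", "sample_rate", "seed"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(session_config, args)
}

#' Run a reproducible closed-loop oxygen-administration session
#'
#' Simulates the full system one second at a time: the virtual patient's
#' true saturation parameterizes PPG synthesis; the stream is demultiplexed,
#' ambient-corrected, filtered and turned into a vitals record; the record
#' crosses the transport link to the controller, which titrates the oxygen
#' flow once per minute (stopping immediately on signal loss and restarting
#' via the watchdog on staleness); the commanded flow then drives the
#' patient over the next second.
#'
#' @param config A [session_config()].
#' @return An object of class `oxloop_session`: data frames `vitals` (one
#'   record per second), `commands` (valve commands), `patient` (per-second
#'   true saturation and inflow), a list `displays` of display transitions,
#'   a `summary` list (steady-state statistics over the final 5 minutes),
#'   and the `config`.
#' @examples
#' \donttest{
#' ses <- run_closed_loop(session_config(duration = 180, seed = 7))
#' summary(ses)
#' }
#' @export
run_closed_loop <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(as.integer(config$seed))

  n_sec <- floor(config$duration)
  fs_cyc <- config$sample_rate / 4
  profile <- config$profile
  profile$seed <- NULL
  patient <- config$patient
  patient$seed <- NULL
  ctrl <- config$controller
  link <- config$transport

  synth <- synth_state_init(profile, config$sample_rate)
  vstate <- vitals_state_init(fs_cyc, config$vitals)

  finger_absent <- function(t) {
    if (is.null(config$no_finger)) return(FALSE)
    any(vapply(config$no_finger,
               function(iv) t >= iv[1] && t < iv[2], logical(1)))
  }

  vitals <- vector("list", n_sec)
  cmds <- list()
  pat_log <- vector("list", n_sec)
  displays <- list()
  last_display <- ""

  for (t in seq_len(n_sec) - 1) {
    true_now <- patient$true_spo2
    flow_now <- ctrl$current_flow
    valid_now <- !finger_absent(t)

    # sensor side: one second of multiplexed samples at the current truth
    em <- synth_emit(synth, fs_cyc,
                     spo2 = min(100, max(70, true_now)), valid = valid_now)
    synth <- em$state
    stream_sec <- em$base + em$ac + em$noise

    red <- stream_sec[seq(1, length(stream_sec), by = 4)]
    ir <- stream_sec[seq(3, length(stream_sec), by = 4)]
    ref <- stream_sec[seq(2, length(stream_sec), by = 2)]
    cyc <- seq_along(red)
    red <- red - ref[ifelse(cyc == 1, 1L, 2L * (cyc - 1L))]
    ir <- ir - ref[2L * cyc - 1L]

    tick <- vitals_tick(vstate, red, ir, t)
    vstate <- tick$state
    vitals[[t + 1]] <- tick$record

    # delivery side
    tx <- transmit(link, tick$record)
    link <- tx$link
    if (tx$delivered) {
      h <- handle_record(ctrl, tx$record)
      ctrl <- h$state
      if (!is.null(h$command)) cmds[[length(cmds) + 1]] <- h$command
      if (!identical(h$display, last_display)) {
        displays[[length(displays) + 1]] <- list(t = t, display = h$display)
        last_display <- h$display
      }
    }
    wd <- watchdog_check(ctrl, now = t)
    ctrl <- wd$state
    if (!is.null(wd$command)) cmds[[length(cmds) + 1]] <- wd$command

    pat_log[[t + 1]] <- data.frame(t = t, true_spo2 = true_now,
                                   flow_in = flow_now)
    patient <- step_patient(patient, ctrl$current_flow, dt = 1)
  }

  vitals <- do.call(rbind, vitals)
  class(vitals) <- c("vitals_log", "data.frame")
  commands <- if (length(cmds) > 0) do.call(rbind, cmds)
              else data.frame(t = numeric(0), flow = numeric(0),
                              voltage = numeric(0), reason = character(0))
  pat_df <- do.call(rbind, pat_log)

  tail_win <- pat_df[pat_df$t >= n_sec - 300, ]
  est_tail <- vitals[vitals$t >= n_sec - 300 & vitals$valid, ]
  summ <- list(
    duration = n_sec,
    steady_mean_spo2 = mean(tail_win$true_spo2),
    steady_sd_spo2 = stats::sd(tail_win$true_spo2),
    steady_mean_est_spo2 = if (nrow(est_tail) > 0) mean(est_tail$spo2) else NA_real_,
    steady_mean_flow = mean(tail_win$flow_in),
    frac_in_band = mean(tail_win$true_spo2 >= ctrl$band[1] &
                          tail_win$true_spo2 <= ctrl$band[2]),
    records_delivered = link$delivered,
    records_dropped = link$dropped)

  structure(list(vitals = vitals, commands = commands, patient = pat_df,
                 displays = displays, summary = summ, config = config),
            class = "oxloop_session")
}

#' @export
print.oxloop_session <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<oxloop_session> %d s closed-loop run, seed %d\n",
              s$duration, x$config$seed))
  cat(sprintf("  steady-state (final 5 min): true SpO2 %.2f%% (sd %.2f), flow %.2f L/min, %.0f%% of time in band\n",
              s$steady_mean_spo2, s$steady_sd_spo2, s$steady_mean_flow,
              100 * s$frac_in_band))
  cat(sprintf("  %d valve commands, %d/%d records delivered\n",
              nrow(x$commands), s$records_delivered,
              s$records_delivered + s$records_dropped))
  invisible(x)
}

#' @export
summary.oxloop_session <- function(object, ...) {
  object$summary
}

#' Plot a closed-loop session
#'
#' Two panels: true and estimated saturation with the target band, and the
#' commanded oxygen flow.
#'
#' @param x An `oxloop_session`.
#' @param ... Unused.
#' @export
plot.oxloop_session <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  band <- x$config$controller$band
  graphics::plot(x$patient$t / 60, x$patient$true_spo2, type = "l",
                 xlab = "time (min)", ylab = "SpO2 (%)",
                 main = "closed-loop oxygen titration",
                 ylim = range(c(x$patient$true_spo2, band)) + c(-1, 1))
  ok <- x$vitals$valid
  graphics::lines(x$vitals$t[ok] / 60, x$vitals$spo2[ok],
                  col = "grey50", lty = 2)
  graphics::abline(h = band, col = "red3", lty = 3)
  graphics::legend("bottomright", c("true", "estimated", "target band"),
                   col = c("black", "grey50", "red3"), lty = c(1, 2, 3),
                   bty = "n", cex = 0.8)
  graphics::plot(x$patient$t / 60, x$patient$flow_in, type = "s",
                 xlab = "time (min)", ylab = "flow (L/min)")
  invisible(x)
}

# --- log serialization -----------------------------------------------------

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write / read session logs
#'
#' Vitals logs: columns `t`, `spo2`, `heart_rate`, `perfusion_index`,
#' `valid`, `r_ratio`. Command logs: `t`, `flow`, `voltage`, `reason`.
#' Patient logs: `t`, `true_spo2`, `flow_in`. CSV values carry 17
#' significant digits and JSONL uses full-precision numbers, so a write /
#' read round trip reproduces the records exactly and identical sessions
#' produce byte-identical files. Malformed files raise a parse error naming
#' the offending line and field.
#'
#' @param records A vitals, command, or patient data frame.
#' @param path File path; `.jsonl` paths use JSON-lines, anything else CSV.
#' @return Writers return `path` invisibly; readers return the data frame.
#' @export
write_vitals_log <- function(records, path) {
  write_typed_log(records,
                  c(t = "n", spo2 = "n", heart_rate = "n",
                    perfusion_index = "n", valid = "l", r_ratio = "n"),
                  path)
}

#' @rdname write_vitals_log
#' @export
read_vitals_log <- function(path) {
  df <- read_typed_log(path, c(t = "n", spo2 = "n", heart_rate = "n",
                               perfusion_index = "n", valid = "l",
                               r_ratio = "n"))
  class(df) <- c("vitals_log", "data.frame")
  df
}

#' @rdname write_vitals_log
#' @export
write_command_log <- function(records, path) {
  write_typed_log(records, c(t = "n", flow = "n", voltage = "n",
                             reason = "c"), path)
}

#' @rdname write_vitals_log
#' @export
read_command_log <- function(path) {
  read_typed_log(path, c(t = "n", flow = "n", voltage = "n", reason = "c"))
}

#' @rdname write_vitals_log
#' @export
write_patient_log <- function(records, path) {
  write_typed_log(records, c(t = "n", true_spo2 = "n", flow_in = "n"), path)
}

#' @rdname write_vitals_log
#' @export
read_patient_log <- function(path) {
  read_typed_log(path, c(t = "n", true_spo2 = "n", flow_in = "n"))
}

# schema: named character vector, "n" numeric, "l" logical, "c" character
write_typed_log <- function(df, schema, path) {
  cols <- names(schema)
  if (!all(cols %in% names(df)))
    stop(sprintf("log is missing column(s): %s",
                 paste(setdiff(cols, names(df)), collapse = ", ")),
         call. = FALSE)
  df <- df[, cols, drop = FALSE]
  if (grepl("\\.jsonl$", path)) {
    # hand-rolled flat-object serialization: numbers carry 17 significant
    # digits so a write/read round trip is bit-exact
    fields <- lapply(cols, function(cn) {
      v <- df[[cn]]
      body <- switch(schema[[cn]],
                     n = ifelse(is.na(v), "null", sprintf("%.17g", v)),
                     l = ifelse(v, "true", "false"),
                     c = paste0("\"", gsub("\"", "\\\\\"", as.character(v)), "\""))
      paste0("\"", cn, "\":", body)
    })
    lines <- paste0("{", do.call(paste, c(fields, sep = ",")), "}")
    writeLines(lines, path)
  } else {
    body <- do.call(paste, c(lapply(cols, function(cn) {
      v <- df[[cn]]
      switch(schema[[cn]], n = fmt_num(v), l = as.character(v),
             c = as.character(v))
    }), sep = ","))
    writeLines(c(paste(cols, collapse = ","), body), path)
  }
  invisible(path)
}

read_typed_log <- function(path, schema) {
  cols <- names(schema)
  empty <- function() {
    out <- lapply(schema, function(ty) switch(ty, n = numeric(0),
                                              l = logical(0), c = character(0)))
    names(out) <- cols
    as.data.frame(out)
  }
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(empty())
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop(sprintf(
                        "parse error at line %d of %s: %s", i, path,
                        conditionMessage(e)), call. = FALSE))
      miss <- setdiff(cols, names(rec))
      if (length(miss) > 0)
        stop(sprintf("parse error at line %d of %s: missing field `%s`",
                     i, path, miss[1]), call. = FALSE)
      rec[vapply(rec, is.null, logical(1))] <- NA
      as.data.frame(rec[cols])
    })
    df <- do.call(rbind, rows)
  } else {
    first <- readLines(path, n = 1)
    if (length(first) == 0) return(empty())
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0 && ncol(df) <= 1) return(empty())
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stop(sprintf("parse error in %s: missing field `%s`", path, miss[1]),
           call. = FALSE)
    df <- df[, cols, drop = FALSE]
  }
  for (cn in cols) {
    ty <- schema[[cn]]
    v <- df[[cn]]
    conv <- switch(ty, n = suppressWarnings(as.numeric(v)),
                   l = as.logical(v), c = as.character(v))
    bad <- which(!is.na(v) & is.na(conv) & !(v %in% c("NA", "null")))
    if (length(bad) > 0)
      stop(sprintf("parse error at line %d of %s: field `%s` has value `%s`",
                   bad[1] + 1, path, cn, v[bad[1]]), call. = FALSE)
    df[[cn]] <- conv
  }
  rownames(df) <- NULL
  df
}

#' Write all logs of a session to a directory
#'
#' Produces `vitals.csv`, `commands.csv`, `patient.csv` and `summary.json`.
#'
#' @param session An `oxloop_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_logs <- function(session, dir) {
  stopifnot(inherits(session, "oxloop_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vitals_log(session$vitals, file.path(dir, "vitals.csv"))
  write_command_log(session$commands, file.path(dir, "commands.csv"))
  write_patient_log(session$patient, file.path(dir, "patient.csv"))
  jsonlite::write_json(session$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
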