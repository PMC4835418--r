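#' Design one of the three PPG processing filters
#'
#' The reader extracts the baseline (DC) and pulsatile (AC) components of
#' each PPG channel with a fixed three-filter cascade:
#' \describe{
#'   \item{`DC_TRACK`}{2nd-order low-pass IIR Butterworth, cutoff 0.1 Hz —
#'     tracks the DC component.}
#'   \item{`DC_REMOVE`}{4th-order high-pass IIR Butterworth, stop band at
#'     0.1 Hz, pass band from 0.5 Hz — removes the baseline ahead of the AC
#'     path. The paper-style specification gives stop/pass edges only; this
#'     implementation places the half-power (-3 dB) point at 0.4 Hz so the
#'     0.5 Hz pass edge keeps gain above 0.9 while 0.1 Hz is attenuated by
#'     about 48 dB.}
#'   \item{`NOISE_LP`}{10th-order low-pass FIR (11 taps), Kaiser window with
#'     beta = 0.5, cutoff 10 Hz — removes noise from the AC component.}
#' }
#' All three preserve the 0.5--4.0 Hz PPG band.
#'
#' @param kind One of `"DC_TRACK"`, `"DC_REMOVE"`, `"NOISE_LP"`.
#' @param fs Sampling rate of the channel in samples/s (125 at the default
#'   acquisition rate). Must exceed twice the highest critical frequency.
#' @return An object of class `filter_spec`: the kind, family, order,
#'   critical frequencies, coefficient vectors `b` and `a`, the sampling
#'   rate, and `settle_samples`, an estimate of the impulse-response
#'   settling length (smallest n with less than 0.1\% of the total absolute
#'   impulse mass remaining).
#' @examples
#' fs <- design_filter("DC_TRACK", 125)
#' abs(filter_response(fs, 0))  # unity DC gain
#' @export
design_filter <- function(kind = c("DC_TRACK", "DC_REMOVE", "NOISE_LP"), fs) {
  kind <- match.arg(kind)
  check_range(fs, "fs", 0, Inf, open_lo = TRUE)
  nyq <- fs / 2
  spec <- switch(kind,
    DC_TRACK = list(family = "butterworth-iir", order = 2L,
                    critical = 0.1, window_param = NA_real_),
    DC_REMOVE = list(family = "butterworth-iir", order = 4L,
                     critical = c(stop = 0.1, pass = 0.5, cutoff = 0.4),
                     window_param = NA_real_),
    NOISE_LP = list(family = "fir-kaiser", order = 10L,
                    critical = 10, window_param = 0.5))
  if (nyq <= max(spec$critical))
    stop(sprintf("fs = %g too low for %s (needs fs > %g)", fs, kind,
                 2 * max(spec$critical)), call. = FALSE)
  coef <- switch(kind,
    DC_TRACK = signal::butter(2, 0.1 / nyq, type = "low"),
    DC_REMOVE = signal::butter(4, 0.4 / nyq, type = "high"),
    NOISE_LP = {
      b <- as.numeric(signal::fir1(10, 10 / nyq, type = "low",
                                   window = signal::kaiser(11, 0.5)))
      # normalize taps to exact unity DC gain (the windowed design alone
      # does not guarantee it)
      list(b = b / sum(b), a = 1)
    })
  out <- structure(c(list(kind = kind, fs = fs,
                          b = as.numeric(coef$b), a = as.numeric(coef$a)),
                     spec, list(settle_samples = NA_integer_)),
                   class = "filter_spec")
  out$settle_samples <- settle_length(out)
  out
}

# Impulse-response settling length: smallest n such that the remaining
# absolute impulse mass beyond n is < 0.1% of the total.
settle_length <- function(spec, horizon_s = 60, tol = 1e-3) {
  n <- ceiling(horizon_s * spec$fs)
  h <- apply_stream(spec, c(1, numeric(n - 1)))$y
  cum <- rev(cumsum(rev(abs(h))))
  idx <- which(cum < tol * cum[1])
  if (length(idx) == 0) n else idx[1]
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s: %s order %d at fs = %g Hz (settles in ~%d samples)\n",
              x$kind, x$family, x$order, x$fs, x$settle_samples))
  invisible(x)
}

#' Complex frequency response of a designed filter
#'
#' Evaluates H(f) = B(e^{-i 2 pi f / fs}) / A(e^{-i 2 pi f / fs}) directly
#' from the coefficient polynomials.
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies in Hz (vectorized).
#' @return Complex response values.
#' @export
filter_response <- function(spec, f) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- 2 * pi * f / spec$fs
  ev <- function(coefs, w) {
    k <- seq_along(coefs) - 1
    vapply(w, function(wi) sum(coefs * exp(-1i * wi * k)), complex(1))
  }
  ev(spec$b, w) / ev(spec$a, w)
}

#' Apply a filter to a chunk of samples, carrying state across chunks
#'
#' Streaming direct-form application: filtering a signal in chunks, passing
#' the returned state into the next call, is sample-identical to filtering
#' the whole signal at once. The state holds the trailing inputs and outputs
#' a direct-form I realization needs.
#'
#' @param spec A `filter_spec`.
#' @param x Numeric chunk (may be empty).
#' @param state `NULL` for a zero-initialized (cold) start, the `state`
#'   returned by the previous call, or [filter_init_state()] for a
#'   steady-state start.
#' @return A list with `y` (filtered chunk) and `state` (to pass on).
#' @examples
#' fsp <- design_filter("NOISE_LP", 125)
#' r1 <- apply_stream(fsp, c(1, numeric(10)))
#' all.equal(r1$y, fsp$b)  # impulse response of an FIR = its taps
#' @export
apply_stream <- function(spec, x, state = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  b <- spec$b; a <- spec$a
  nb <- length(b); na_ <- length(a)
  if (is.null(state))
    state <- list(x = numeric(nb - 1), y = numeric(na_ - 1))
  if (length(state$x) != nb - 1 || length(state$y) != na_ - 1)
    stop("filter state does not match the filter specification", call. = FALSE)
  n <- length(x)
  if (n == 0) return(list(y = numeric(0), state = state))

  xx <- c(state$x, as.numeric(x))
  if (nb > 1) {
    v <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))
    v <- v[nb:length(xx)]
  } else {
    v <- b * as.numeric(x)
  }
  if (na_ > 1) {
    v <- v / a[1]
    y <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive",
                                  init = rev(state$y)))
  } else {
    y <- v / a[1]
  }
  list(y = y,
       state = list(x = if (nb > 1) xx[(length(xx) - nb + 2):length(xx)] else numeric(0),
                    y = if (na_ > 1) utils::tail(c(state$y, y), na_ - 1) else numeric(0)))
}

#' Steady-state filter state for a constant input level
#'
#' Returns the state [apply_stream()] would have after an infinitely long
#' constant input `x0`: trailing inputs all `x0`, trailing outputs all
#' `H(0) x0`. Starting a stream from this state suppresses the start-up
#' transient that a cold (zero) state would produce on a signal with a large
#' DC pedestal.
#'
#' @param spec A `filter_spec`.
#' @param x0 The constant input level.
#' @return A state list for [apply_stream()].
#' @export
filter_init_state <- function(spec, x0) {
  stopifnot(inherits(spec, "filter_spec"))
  g0 <- sum(spec$b) / sum(spec$a)
  list(x = rep(x0, length(spec$b) - 1),
       y = rep(g0 * x0, length(spec$a) - 1))
}

# Streaming three-filter chain over one channel: DC via DC_TRACK, AC via
# NOISE_LP(DC_REMOVE(x)). States are initialized at the first sample's level
# so the DC pedestal produces no start-up transient.
chain_init <- function(fs, x0 = 0) {
  dc <- design_filter("DC_TRACK", fs)
  hp <- design_filter("DC_REMOVE", fs)
  lp <- design_filter("NOISE_LP", fs)
  list(fs = fs,
       dc = dc, hp = hp, lp = lp,
       dc_state = filter_init_state(dc, x0),
       hp_state = filter_init_state(hp, x0),
       lp_state = filter_init_state(lp, 0),
       warmup = max(dc$settle_samples, hp$settle_samples + lp$settle_samples))
}

chain_push <- function(chain, x) {
  r_dc <- apply_stream(chain$dc, x, chain$dc_state)
  r_hp <- apply_stream(chain$hp, x, chain$hp_state)
  r_lp <- apply_stream(chain$lp, r_hp$y, chain$lp_state)
  chain$dc_state <- r_dc$state
  chain$hp_state <- r_hp$state
  chain$lp_state <- r_lp$state
  list(dc = r_dc$y, ac = r_lp$y, chain = chain)
}

#' Split a PPG channel into AC and DC components
#'
#' Runs the three-filter cascade over a whole channel series: the DC track is
#' the 0.1 Hz low-pass output; the AC path is the 0.5 Hz high-pass followed
#' by the 10 Hz FIR noise filter. Filter states are initialized at the first
#' level of the first second (an instant DC estimate), so the DC pedestal
#' produces no start-up transient;
#' `warmup_samples` still reports the settling estimate of the slowest path
#' and windows overlapping it should be treated with care.
#'
#' @param x Numeric channel series (ambient-corrected).
#' @param fs Channel sampling rate, samples/s.
#' @return An object of class `component_pair`: `ac`, `dc`, `fs`,
#'   `warmup_samples`.
#' @examples
#' cp <- extract_components(rep(2, 500), fs = 125)
#' max(abs(cp$ac))      # ~0: constant input has no pulsatile part
#' mean(cp$dc)          # ~2
#' @export
extract_components <- function(x, fs) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  chain <- chain_init(fs, x0 = mean(x[seq_len(min(length(x), fs))]))
  out <- chain_push(chain, x)
  structure(list(ac = out$ac, dc = out$dc, fs = fs,
                 warmup_samples = chain$warmup),
            class = "component_pair")
}

#' Export / import filter coefficients as CSV
#'
#' Columns: `coef` (`"b"` or `"a"`), `index` (0-based tap index), `value`
#' (17 significant digits). Useful for cross-checking a design against an
#' external tool.
#'
#' @param spec A `filter_spec`.
#' @param path File path.
#' @return `write_filter_csv` returns `path` invisibly; `read_filter_csv`
#'   returns a list with numeric `b` and `a`.
#' @export
write_filter_csv <- function(spec, path) {
  stopifnot(inherits(spec, "filter_spec"))
  lines <- c("coef,index,value",
             sprintf("b,%d,%.17g", seq_along(spec$b) - 1, spec$b),
             sprintf("a,%d,%.17g", seq_along(spec$a) - 1, spec$a))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_filter_csv
#' @export
read_filter_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer", "numeric"))
  if (!all(c("coef", "index", "value") %in% names(df)))
    stop("filter CSV must have columns coef, index, value", call. = FALSE)
  list(b = df$value[df$coef == "b"][order(df$index[df$coef == "b"]) ],
       a = df$value[df$coef == "a"][order(df$index[df$coef == "a"]) ])
}
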