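# Internal helpers shared across modules.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. seed = NULL means "use the ambient RNG as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Scalar numeric check with a range; used by the constructors.
check_range <- function(x, name, lo = -Inf, hi = Inf,
                        open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}
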