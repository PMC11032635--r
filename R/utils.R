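# Internal helpers: classed errors and argument checks.

stop_mp <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "midpointr_error", "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mp(sprintf("`%s` must be a single finite number", name), "invalid_argument")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    b_lo <- if (strict_lower) "(" else "["
    b_hi <- if (strict_upper) ")" else "]"
    stop_mp(sprintf("`%s` = %g is outside %s%g, %g%s", name, x, b_lo, lower, upper, b_hi),
            "invalid_argument")
  }
  as.numeric(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-condition RNG substream seed deterministically from a base seed,
# without disturbing the caller's RNG state.
substream_seed <- function(seed, condition) {
  idx <- match(condition, conflict_conditions)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, 3L)[idx]
}

# Cumulative trapezoidal integral of y sampled on a uniform grid with step h;
# returns a vector the same length as y, starting at 0.
cumtrapz_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1L] + y[-n]) / 2) * h)
}
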