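# Internal helpers shared across modules.

abort_invalid <- function(msg, class = "ergkit_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_parse <- function(msg) {
  abort_invalid(msg, class = "ergkit_parse_error")
}

abort_io <- function(msg) {
  abort_invalid(msg, class = "ergkit_io_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded internals do not
#' disturb the user's random stream. All exported stochastic operations in
#' ergkit route their randomness through this helper.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_scalar_number(seed)) abort_invalid("seed must be a single number")
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
  expr
}

# Uniform-grid check used by recording validation (relative tolerance on the
# sample interval).
check_uniform_time <- function(time, rel_tol = 1e-6, context = "recording") {
  if (length(time) < 2L) abort_invalid(sprintf("%s: need >= 2 samples", context))
  dt <- diff(time)
  if (any(dt <= 0)) {
    abort_parse(sprintf("%s: time must be strictly increasing", context))
  }
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > rel_tol * dt0)) {
    abort_parse(sprintf("%s: non-uniform time grid (max deviation %.3g ms)",
                        context, max(abs(dt - dt0))))
  }
  dt0
}

# Linear interpolation read-off at a single time point.
interp_at <- function(time, voltage, t0) {
  stats::approx(time, voltage, xout = t0, rule = 1)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
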