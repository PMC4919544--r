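# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All generators in the package route their randomness through this helper so
#' that a fixed seed gives byte-identical output without clobbering the
#' session RNG stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with sprintf-style formatting and no call in the condition
cq_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# scalar checks used by nearly every exported function
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    cq_stop("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    cq_stop("`%s` must be > %s (got %s)", name, format(lower), format(x))
  }
  if (!strict_lower && x < lower) {
    cq_stop("`%s` must be >= %s (got %s)", name, format(lower), format(x))
  }
  if (x > upper) cq_stop("`%s` must be <= %s (got %s)", name, format(upper), format(x))
  invisible(x)
}

check_fraction <- function(x, name, allow_one = TRUE) {
  check_scalar_number(x, name, lower = 0)
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (x > hi) cq_stop("`%s` must be in [0,%s]", name, if (allow_one) "1" else "1)")
  invisible(x)
}
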