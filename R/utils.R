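# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ns <- function(...) stop(..., call. = FALSE)

#' Split a master seed into independent sub-seeds
#'
#' Deterministically derives `n` sub-seeds from one master seed so that each
#' pipeline stage (tree simulation, environment fields, placement,
#' permutation tests, ...) consumes its own stream. All derived seeds are
#' strictly positive and below 2^31.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`.
#' @keywords internal
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
# seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop_ns(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_ns(sprintf("`%s` must be > %s (got %s)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_ns(sprintf("`%s` must be >= %s (got %s)", name, min, x))
  }
  invisible(x)
}
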