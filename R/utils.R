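# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`
#' and restores the previous state on exit, so seeded package functions
#' never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' One master seed spawns independent, deterministic streams for
#' sub-tasks (marker sampling, CV partitions, simulation) so that any
#' subset of an experiment can be reproduced in isolation. Plain integer
#' arithmetic below 2^31, no RNG involved.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer indices identifying the
#'   sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L, all(idx >= 0))
  m <- 2147483629                       # prime below 2^31
  x <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    x <- (x * 48271 + as.numeric(idx[k]) * 16807 + 104729 * k) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

check_positive_scalar <- function(x, name, int = FALSE, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  if (int && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
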