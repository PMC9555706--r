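# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

PM_MAX <- 1000

clip_pm <- function(x, lo = 0, hi = PM_MAX) pmin(pmax(x, lo), hi)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible sub-stream seed
#'
#' Expands one user-facing seed into independent per-stream seeds via a
#' counter scheme, so that e.g. adding a site does not reshuffle the random
#' streams of existing sites. Kept below 2^31 so the result is a valid R seed.
#'
#' @param seed integer master seed.
#' @param ... one or more non-negative integer stream counters.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(s)
}

# Run an expression with a local RNG state (restores caller's state).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
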