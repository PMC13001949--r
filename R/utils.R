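#' Evaluate an expression under a fixed RNG seed
#'
#' All randomness in the package flows through this helper: the global RNG
#' state is saved, the seed installed, and the prior state restored on exit,
#' so seeded runs are reproducible and never disturb the caller's RNG.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a master seed (kept < 2^31).
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + as.integer(stream)) %% 2147483647L
}

abort_fmt <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "rnaphylo_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Watson-Crick + wobble pairs over {A,C,G,U}
ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

is_allowed_pair <- function(x, y) paste0(x, y) %in% ALLOWED_PAIRS
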