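# Small shared helpers: seeded evaluation, seed derivation, means.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit, so seeded operations never
#' disturb the global random stream.
#'
#' @param seed Integer seed; `NULL` evaluates without touching the RNG.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child RNG seed deterministically
#'
#' Hashes a root seed together with integer stream identifiers (e.g. level
#' and replicate indices) into a new seed below 2^31, so each operator
#' invocation gets an independent, reproducible stream.
#'
#' @param seed Root integer seed.
#' @param ... Integer identifiers of the substream.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (x in ids) {
    # 32-bit mixing done in double precision; all intermediates < 2^52
    h <- (h * 69069 + as.numeric(x) + 1) %% 2147483647
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h)
}

harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  length(x) / sum(1 / x)
}

geometric_mean <- function(x) exp(mean(log(x)))

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}
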