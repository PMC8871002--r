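# Internal helpers shared across modules.

#' @useDynLib saxfcn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
# All package randomness funnels through this so results are pure functions
# of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Half-up rounding (R's round() is round-half-even); 127.5 -> 128.
round_half_up <- function(x) floor(x + 0.5)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
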