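#' @importFrom rlang abort warn %||%
#' @importFrom stats quantile rnorm runif sd predict
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' One global seed is expanded into per-stage seeds (kernel sampling, trial
#' selection, per-repeat, per-subject, ...) through a fixed multiplicative
#' hash, so every random stage is independently reproducible. All arithmetic
#' stays below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer indices naming the stage.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) + 11) %% m
  }
  as.integer(h)
}

# shared input checks ---------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "rocketfp_invalid_input")
  }
  invisible(as.integer(x))
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "rocketfp_invalid_input")
  }
  invisible(as.numeric(x))
}

invalid_input <- function(msg) {
  abort(msg, class = "rocketfp_invalid_input")
}
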