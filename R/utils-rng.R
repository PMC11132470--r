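#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort %||%
#' @importFrom stats fft rnorm runif rbinom approx sd var cor qt pt lm coef
#'   setNames complete.cases optim median quantile
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive `n` independent sub-seeds from a master seed. All package-internal
# randomness flows through streams derived this way, so a single master seed
# reproduces a whole pipeline run.
stream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}

clip01 <- function(x) pmin(1, pmax(0, x))

rms <- function(x) sqrt(mean(x^2))
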