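# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial rounding used for all printed currency conversions: exact
#' halves round up in magnitude, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(2.675, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's RNG stream.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one global seed into per-module streams.
# Lehmer-style step keeps results in [0, 2^31 - 2], valid for set.seed().
sub_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + 113 * offset) %% m)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# gamma draws parameterised by mean and coefficient of variation; cv = 0
# degenerates to the mean exactly (used when noise is switched off).
rgamma_mean_cv <- function(n, mean, cv) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (cv <= 0) return(mean)
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}
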