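# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards. All generators route their randomness through this so
#' that they are pure functions of (inputs, seed) and never leak RNG state.
#'
#' @param seed integer scalar seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# Derive a child seed from a parent seed and a stream index; keeps every
# stage on its own reproducible substream while staying inside 32-bit range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647 * 1103 +
                as.numeric(stream) * 12347) %% 2147483647)
}

# Multiplicative log-normal noise with unit mean and coefficient of
# variation cv (cv = 0 returns 1s exactly).
lognormal_noise <- function(n, cv) {
  stopifnot(cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

stop_param <- function(...) stop(..., call. = FALSE)

# Trapezoidal quadrature weights for an arbitrary strictly increasing grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
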