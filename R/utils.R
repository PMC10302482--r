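## Small internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' All stochastic operations in the package take an explicit integer seed and
#' route their randomness through this helper, so no function mutates the
#' global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

## degree/radian conversion; torsions are user-facing in degrees
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap an angle in degrees into [-180, 180)
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
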