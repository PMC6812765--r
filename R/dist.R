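#' Specify a univariate sampling distribution
#'
#' Small declarative specs used by the synthetic-scene generator for the
#' suspension-diameter and aspect-ratio draws. Truncation bounds are enforced
#' by rejection sampling.
#'
#' @param dist one of `"normal"`, `"lognormal"`, `"uniform"`, `"fixed"`.
#' @param mean,sd mean and standard deviation of the (untruncated)
#'   distribution; for `"lognormal"` these are the mean and sd of the
#'   distribution itself, not of its logarithm.
#' @param min,max truncation bounds (rejection sampling).
#' @param value the constant for `dist = "fixed"`.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("normal", mean = 0.20, sd = 0.04, min = 0, max = 1)
#' @export
dist_spec <- function(dist = c("normal", "lognormal", "uniform", "fixed"),
                      mean = NULL, sd = NULL, min = -Inf, max = Inf,
                      value = NULL) {
  dist <- match.arg(dist)
  if (dist %in% c("normal", "lognormal")) {
    stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
    if (dist == "lognormal" && mean <= 0)
      stop("lognormal mean must be positive")
  }
  if (dist == "uniform") stopifnot(is.finite(min), is.finite(max), min < max)
  if (dist == "fixed") stopifnot(is.numeric(value))
  stopifnot(min < max || dist == "fixed")
  structure(list(dist = dist, mean = mean, sd = sd, min = min, max = max,
                 value = value),
            class = "dist_spec")
}

#' Draw from a distribution spec
#'
#' @param n number of draws.
#' @param spec a [dist_spec()].
#' @param max_tries rejection-sampling retry budget per batch; exceeded
#'   truncation bounds raise an error rather than looping forever.
#' @return Numeric vector of length `n` within `[spec$min, spec$max]`.
#' @export
draw_dist <- function(n, spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (spec$dist == "fixed") {
    if (spec$value < spec$min || spec$value > spec$max)
      stop("fixed value outside truncation bounds")
    return(rep(spec$value, n))
  }
  raw <- switch(spec$dist,
    normal    = function(m) rnorm(m, spec$mean, spec$sd),
    lognormal = function(m) {
      sdlog <- sqrt(log(1 + (spec$sd / spec$mean)^2))
      meanlog <- log(spec$mean) - sdlog^2 / 2
      rlnorm(m, meanlog, sdlog)
    },
    uniform   = function(m) runif(m, spec$min, spec$max))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    if (tries >= max_tries)
      stop("rejection sampling exhausted ", max_tries,
           " tries; distribution mass outside [min, max] too large")
    x <- raw(max(n - length(out), n))
    out <- c(out, x[x >= spec$min & x <= spec$max])
    tries <- tries + 1L
  }
  out[seq_len(n)]
}
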