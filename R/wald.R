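#' Wald (inverse-Gaussian) first-passage time distribution
#'
#' First-passage time of a drift-diffusion accumulator with constant drift
#' `drift`, diffusion SD `sigma` (per sqrt time unit) and a single absorbing
#' boundary. The FPT is inverse-Gaussian with mean `mu = boundary / drift`
#' and shape `lambda = (boundary / sigma)^2`:
#' `f(t) = sqrt(lambda / (2 pi t^3)) exp(-lambda (t - mu)^2 / (2 mu^2 t))`.
#'
#' All arguments are vectorised; times at or below zero get density 0
#' (cumulative probability 0). The CDF is evaluated on the log scale in its
#' second term to avoid overflow of `exp(2 lambda / mu)` for small noise.
#'
#' @param t Time (same unit as the drift's time base; ms throughout the
#'   package).
#' @param drift Drift rate (> 0).
#' @param sigma Diffusion noise SD (> 0).
#' @param boundary Absorbing boundary (default 1).
#' @param log,lower.tail As in standard distribution functions.
#' @return `fpt_density()` the density, `fpt_cdf()` the distribution
#'   function, `fpt_sample()` `n` random first-passage times.
#' @export
fpt_density <- function(t, drift, sigma, boundary = 1, log = FALSE) {
  stopifnot(all(drift > 0), all(sigma > 0), all(boundary > 0))
  mu <- boundary / drift
  lambda <- (boundary / sigma)^2
  n <- max(length(t), length(mu), length(lambda))
  t <- rep_len(t, n); mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  ld <- rep(-Inf, n)
  ok <- t > 0
  ld[ok] <- 0.5 * (log(lambda[ok]) - log(2 * pi) - 3 * log(t[ok])) -
    lambda[ok] * (t[ok] - mu[ok])^2 / (2 * mu[ok]^2 * t[ok])
  if (log) ld else exp(ld)
}

#' @rdname fpt_density
#' @export
fpt_cdf <- function(t, drift, sigma, boundary = 1, lower.tail = TRUE) {
  stopifnot(all(drift > 0), all(sigma > 0), all(boundary > 0))
  mu <- boundary / drift
  lambda <- (boundary / sigma)^2
  n <- max(length(t), length(mu), length(lambda))
  t <- rep_len(t, n); mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  p <- numeric(n)
  ok <- t > 0
  if (any(ok)) {
    sq <- sqrt(lambda[ok] / t[ok])
    a <- stats::pnorm(sq * (t[ok] / mu[ok] - 1))
    # second term on log scale: exp(2 lambda / mu) * pnorm(-sq (t/mu + 1))
    lb <- 2 * lambda[ok] / mu[ok] +
      stats::pnorm(-sq * (t[ok] / mu[ok] + 1), log.p = TRUE)
    p[ok] <- a + exp(lb)
  }
  p <- pmin(pmax(p, 0), 1)
  if (lower.tail) p else 1 - p
}

#' @rdname fpt_density
#' @param n Number of samples.
#' @export
fpt_sample <- function(n, drift, sigma, boundary = 1) {
  stopifnot(all(drift > 0), all(sigma > 0), all(boundary > 0))
  mu <- rep_len(boundary / drift, n)
  lambda <- rep_len((boundary / sigma)^2, n)
  # Michael, Schucany & Haas (1976) transformation sampler
  z <- stats::rnorm(n)^2
  x <- mu + (mu^2 * z) / (2 * lambda) -
    (mu / (2 * lambda)) * sqrt(4 * mu * lambda * z + mu^2 * z^2)
  u <- stats::runif(n)
  pick_x <- u <= mu / (mu + x)
  out <- ifelse(pick_x, x, mu^2 / x)
  out
}
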