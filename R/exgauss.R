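#' Ex-Gaussian runner distributions
#'
#' Each racing accumulator ("runner") in the SIS model has an ex-Gaussian
#' finish-time distribution: the sum of a Gaussian component (mean `mu`,
#' SD `sigma`) and an exponential component (mean `tau`), all in
#' milliseconds. The runner's running time is summarised by `mu + tau`.
#' Latencies are non-negative by construction of the task clock, so the
#' density is clamped to 0 (and the survivor to 1) for `t <= 0`; for the
#' parameter ranges used here the ex-Gaussian mass below zero is
#' negligible (< 1e-10) and no renormalisation is applied.
#'
#' @param t latency in ms (vectorised).
#' @param mu,sigma,tau ex-Gaussian parameters in ms; all must be positive.
#' @return `dexgauss` the density, `pexgauss` the CDF, `sexgauss` the
#'   survivor function `1 - F(t)`, `rexgauss` a vector of `n` samples.
#' @examples
#' dexgauss(400, mu = 300, sigma = 50, tau = 100)
#' sexgauss(-10, 300, 50, 100)  # 1: a runner cannot finish before it starts
#' mean(rexgauss(1e4, 300, 50, 100))  # close to mu + tau = 400
#' @name exgauss
NULL

check_exg <- function(mu, sigma, tau) {
  if (!all(is.finite(mu), is.finite(sigma), is.finite(tau)) ||
      any(mu <= 0) || any(sigma <= 0) || any(tau <= 0)) {
    stop("ex-Gaussian parameters must be finite and positive (mu, sigma, tau > 0)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname exgauss
#' @export
dexgauss <- function(t, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  z <- (t - mu) / sigma
  # log-scale Mills-ratio form keeps the tail stable when sigma/tau is large
  lg <- -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  d <- exp(lg)
  d[t <= 0 | !is.finite(d)] <- 0
  d
}

#' @rdname exgauss
#' @export
pexgauss <- function(t, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  z <- (t - mu) / sigma
  p <- stats::pnorm(z) -
    exp(sigma^2 / (2 * tau^2) - (t - mu) / tau +
          stats::pnorm(z - sigma / tau, log.p = TRUE))
  p <- pmin(pmax(p, 0), 1)
  p[t <= 0] <- 0
  p
}

#' @rdname exgauss
#' @export
sexgauss <- function(t, mu, sigma, tau) {
  1 - pexgauss(t, mu, sigma, tau)
}

#' @rdname exgauss
#' @param n number of samples.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}
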