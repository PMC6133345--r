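#' Zero-one-inflated beta (ZOIB) density
#'
#' Mixture distribution on the closed unit interval with point masses at 0 and
#' 1 and a beta density on (0, 1), parameterised by the beta mean \eqn{\mu},
#' precision \eqn{\phi} (sum of the two beta shape parameters), the zero
#' probability \eqn{p_0 = \Pr(y = 0)} and the *conditional* one probability
#' \eqn{p_1 = \Pr(y = 1 \mid y > 0)}:
#' \deqn{f(y) = p_0 \, [y = 0] + (1-p_0) p_1 \, [y = 1] +
#'       (1-p_0)(1-p_1)\,\mathrm{Beta}(y; \mu\phi, (1-\mu)\phi) \, [0 < y < 1].}
#'
#' This is the likelihood used for the proportion of each six-hour bin a
#' tagged animal spends in the 0--1 m surface layer, where exact 0\% and 100\%
#' bins occur with positive probability.
#'
#' @param x value(s) in \[0, 1\].
#' @param mu beta-component mean, in (0, 1).
#' @param p0 probability of an exact zero, in \[0, 1).
#' @param p1 conditional probability of an exact one given y > 0, in \[0, 1).
#' @param phi beta precision (sum of shape parameters), > 0.
#' @param log logical; return log-density?
#' @return density (or log-density) values, recycled to common length.
#' @examples
#' dzoib(0, mu = 0.5, p0 = 0.3, p1 = 0, phi = 2)   # = 0.3
#' dzoib(0.5, mu = 0.5, p0 = 0, p1 = 0, phi = 2)   # = dbeta(0.5, 1, 1) = 1
#' @export
dzoib <- function(x, mu, p0 = 0, p1 = 0, phi, log = FALSE) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("dzoib: 'x' must lie in [0, 1]")
  }
  n <- max(length(x), length(mu), length(p0), length(p1), length(phi))
  x <- rep_len(x, n); mu <- rep_len(mu, n); p0 <- rep_len(p0, n)
  p1 <- rep_len(p1, n); phi <- rep_len(phi, n)
  stopifnot(all(mu > 0 & mu < 1), all(p0 >= 0 & p0 < 1),
            all(p1 >= 0 & p1 < 1), all(phi > 0))
  ld <- numeric(n)
  i0 <- x == 0; i1 <- x == 1; ii <- !i0 & !i1
  ld[i0] <- log(p0[i0])
  ld[i1] <- log1p(-p0[i1]) + log(p1[i1])
  ld[ii] <- log1p(-p0[ii]) + log1p(-p1[ii]) +
    stats::dbeta(x[ii], mu[ii] * phi[ii], (1 - mu[ii]) * phi[ii], log = TRUE)
  if (log) ld else exp(ld)
}

#' ZOIB expected value
#'
#' Closed-form mean of the zero-one-inflated beta mixture:
#' \eqn{E[y] = (1 - p_0)\,(p_1 + (1 - p_1)\,\mu)}.
#'
#' @inheritParams dzoib
#' @return expected value(s) in \[0, 1\].
#' @export
zoib_mean <- function(mu, p0 = 0, p1 = 0) {
  (1 - p0) * (p1 + (1 - p1) * mu)
}

#' Draw from the ZOIB distribution
#'
#' @param n number of draws.
#' @inheritParams dzoib
#' @return numeric vector of draws in \[0, 1\].
#' @export
rzoib <- function(n, mu, p0 = 0, p1 = 0, phi) {
  mu <- rep_len(mu, n); p0 <- rep_len(p0, n); p1 <- rep_len(p1, n)
  phi <- rep_len(phi, n)
  u <- stats::runif(n)
  y <- numeric(n)
  is0 <- u < p0
  is1 <- !is0 & u < p0 + (1 - p0) * p1
  ii <- !is0 & !is1
  y[is1] <- 1
  if (any(ii)) {
    y[ii] <- stats::rbeta(sum(ii), mu[ii] * phi[ii], (1 - mu[ii]) * phi[ii])
  }
  y
}
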