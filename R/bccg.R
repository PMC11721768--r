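#' The Box-Cox Cole-Green (LMS) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' z-score transform for the three-parameter Box-Cox Cole-Green (BCCG)
#' distribution that underlies the LMS method of centile estimation.  A
#' positive response \eqn{y} is mapped to an (approximately) standard normal
#' z-score by the Box-Cox transform
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\sigma} \quad (\nu \ne 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0),}
#' where \eqn{\mu > 0} is the median, \eqn{\sigma > 0} a coefficient-of-
#' variation-like scale, and \eqn{\nu} the Box-Cox power controlling skewness
#' (\eqn{\nu = 1} recovers a normal with mean \eqn{\mu} and sd \eqn{\mu\sigma};
#' \eqn{\nu = 0} a lognormal).  In LMS notation \eqn{L = \nu}, \eqn{M = \mu},
#' \eqn{S = \sigma}.
#'
#' Because \eqn{y > 0}, the z-score is restricted to \eqn{z > -1/(\nu\sigma)}
#' for \eqn{\nu > 0} (and the mirror-image for \eqn{\nu < 0}).  By default the
#' density is normalized over this truncated support (exact normalization);
#' set \code{truncate = FALSE} to obtain the unnormalized kernel used by most
#' LMS software, which differs by a factor \eqn{\Phi(1/(\sigma|\nu|))} that is
#' negligible for \eqn{\sigma \le 0.2}.  The quantile function and z-score use
#' the plain (untruncated) transform throughout, matching how LMS centiles are
#' read off charts; \code{qbccg} returns the support boundary 0 with a warning
#' when \eqn{1 + \nu\sigma z_p \le 0}.
#'
#' @param y vector of positive scores.
#' @param p vector of probabilities in (0, 1).
#' @param n number of random draws.
#' @param mu median parameter, \eqn{\mu > 0}.
#' @param sigma scale parameter, \eqn{\sigma > 0}.
#' @param nu Box-Cox power (skewness) parameter.
#' @param log logical; return the log-density.
#' @param truncate logical; include the truncation normalization constant in
#'   the density (default \code{TRUE}).
#'
#' @return \code{dbccg} the (log-)density, \code{pbccg} the CDF, \code{qbccg}
#'   quantiles, \code{rbccg} random draws, \code{zbccg} z-scores.  All are
#'   vectorized over the first argument and recycle parameters.
#'
#' @examples
#' qbccg(0.5, mu = 60, sigma = 0.1, nu = -0.3)   # the median is mu
#' zbccg(66, mu = 60, sigma = 0.1, nu = 1)       # one sd above: z = 1
#' @name bccg
NULL

.check_bccg_params <- function(mu, sigma, nu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive and finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be positive and finite")
  if (any(!is.finite(nu))) stop("'nu' must be finite")
}

#' @rdname bccg
#' @export
zbccg <- function(y, mu, sigma, nu) {
  .check_bccg_params(mu, sigma, nu)
  if (any(!is.finite(y)) || any(y <= 0)) stop("'y' must be positive: BCCG support is y > 0")
  r <- log(y / mu)
  # expm1 keeps the nu != 0 branch continuous as nu -> 0
  ifelse(rep_len(nu, length(r)) == 0, r / sigma, expm1(nu * r) / (nu * sigma))
}

#' @rdname bccg
#' @export
qbccg <- function(p, mu, sigma, nu) {
  .check_bccg_params(mu, sigma, nu)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) stop("'p' must lie strictly in (0, 1)")
  z <- stats::qnorm(p)
  nlen <- max(length(p), length(mu), length(sigma), length(nu))
  z <- rep_len(z, nlen); mu <- rep_len(mu, nlen)
  sigma <- rep_len(sigma, nlen); nu <- rep_len(nu, nlen)
  q <- numeric(nlen)
  zero <- nu == 0
  q[zero] <- mu[zero] * exp(sigma[zero] * z[zero])
  if (any(!zero)) {
    a <- 1 + nu[!zero] * sigma[!zero] * z[!zero]
    qi <- ifelse(a > 0,
                 mu[!zero] * exp(log1p(nu[!zero] * sigma[!zero] * z[!zero]) / nu[!zero]),
                 0)
    if (any(a <= 0)) warning("quantile beyond the Box-Cox support boundary; returning 0 (truncated)")
    q[!zero] <- qi
  }
  q
}

#' @rdname bccg
#' @export
pbccg <- function(y, mu, sigma, nu, truncate = TRUE) {
  z <- zbccg(y, mu, sigma, nu)
  p <- stats::pnorm(z)
  if (truncate) {
    nlen <- length(z)
    nu <- rep_len(nu, nlen); sigma <- rep_len(sigma, nlen)
    C <- ifelse(nu == 0, 1, stats::pnorm(1 / (sigma * abs(nu))))
    # for nu > 0 mass below the boundary is excluded; for nu < 0 mass above
    p <- ifelse(nu > 0, (p - (1 - C)) / C, ifelse(nu < 0, p / C, p))
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' @rdname bccg
#' @export
dbccg <- function(y, mu, sigma, nu, log = FALSE, truncate = TRUE) {
  z <- zbccg(y, mu, sigma, nu)
  nlen <- length(z)
  y <- rep_len(y, nlen); mu <- rep_len(mu, nlen)
  sigma <- rep_len(sigma, nlen); nu <- rep_len(nu, nlen)
  ll <- (nu - 1) * log(y / mu) - log(mu * sigma) + stats::dnorm(z, log = TRUE)
  if (truncate) {
    lC <- ifelse(nu == 0, 0, stats::pnorm(1 / (sigma * abs(nu)), log.p = TRUE))
    ll <- ll - lC
  }
  if (log) ll else exp(ll)
}

#' @rdname bccg
#' @export
rbccg <- function(n, mu, sigma, nu) {
  .check_bccg_params(mu, sigma, nu)
  u <- stats::runif(n)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  # map the uniform into the admissible z-region so every draw has y > 0
  C <- ifelse(nu == 0, 1, stats::pnorm(1 / (sigma * abs(nu))))
  z <- ifelse(nu > 0, stats::qnorm(1 - C + u * C),
       ifelse(nu < 0, stats::qnorm(u * C), stats::qnorm(u)))
  ifelse(nu == 0, mu * exp(sigma * z),
         mu * exp(log1p(nu * sigma * z) / nu))
}
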