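#' Wrap an angle onto \eqn{[-\pi, \pi)}
#'
#' All phase angles in the package live on the half-open interval
#' \eqn{[-\pi, \pi)}; every public entry point wraps its angular inputs
#' through this function.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector with each element equal to `theta + 2*pi*n`
#'   for the integer `n` that places it in \eqn{[-\pi, \pi)}.
#' @examples
#' wrap_angle(3 * pi)   # -pi
#' wrap_angle(c(0, 2 * pi, -pi))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0L) {
    stop("`theta` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(theta))) {
    stop("`theta` contains non-finite values", call. = FALSE)
  }
  w <- (theta + pi) %% (2 * pi) - pi
  # %% can return 2*pi - eps for inputs just below a multiple of 2*pi
  w[w >= pi] <- -pi
  w
}

#' Mean resultant of a set of phases
#'
#' The complex average \eqn{(1/K) \sum_k e^{i\theta_k}}, returned as its
#' real and imaginary parts. Its modulus is the inter-trial phase
#' coherence ([itpc()]), its argument the mean phase.
#'
#' @param phases Numeric vector of phase angles in radians (wrapped on entry).
#' @return Named numeric vector with elements `re` and `im`.
#' @seealso [itpc()]
#' @export
mean_resultant <- function(phases) {
  if (!is.numeric(phases) || length(phases) == 0L) {
    stop("`phases` must contain at least one angle", call. = FALSE)
  }
  phases <- wrap_angle(phases)
  c(re = mean(cos(phases)), im = mean(sin(phases)))
}

#' Inter-trial phase coherence
#'
#' The length of the mean resultant: 1 for perfectly phase-locked trials,
#' 0 in expectation-squared-sense for uniform phases. Note that for finite
#' trial counts the ITPC of incoherent phases is positively biased
#' (its square has expectation `1/K`).
#'
#' @inheritParams mean_resultant
#' @return A coherence value in `[0, 1]`.
#' @export
itpc <- function(phases) {
  r <- mean_resultant(phases)
  min(sqrt(r[["re"]]^2 + r[["im"]]^2), 1)
}

#' Wrapped Cauchy density
#'
#' Density of the wrapped Cauchy distribution with circular location `mu`
#' and scale `gamma > 0`:
#' \deqn{p(\theta) = \frac{1}{2\pi}\,
#'   \frac{\sinh\gamma}{\cosh\gamma - \cos(\theta - \mu)}.}
#' The mean resultant is \eqn{e^{i\mu - \gamma}}, so the circular variance
#' is \eqn{S = 1 - e^{-\gamma}}.
#'
#' Evaluation uses the Poisson-kernel form in \eqn{q = e^{-\gamma}},
#' \eqn{\log p = \log(1-q^2) - \log(1 + q^2 - 2q\cos(\theta-\mu)) -
#' \log 2\pi}, which is stable for arbitrarily large `gamma` (no
#' `cosh`/`sinh` overflow).
#'
#' @param theta Numeric vector of angles (radians; wrapped on entry).
#' @param mu Circular location (radians).
#' @param gamma Scale parameter, strictly positive. `gamma = 0` (the
#'   point-mass limit) is rejected.
#' @param log Return the log-density?
#' @return Numeric vector of (log-)densities.
#' @export
dwcauchy <- function(theta, mu = 0, gamma, log = FALSE) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("`mu` must be a single finite angle", call. = FALSE)
  }
  theta <- wrap_angle(theta)
  q <- exp(-gamma)
  d <- theta - mu
  lp <- log1p(-q^2) - log1p(q^2 - 2 * q * cos(d)) - log(2 * pi)
  if (log) lp else exp(lp)
}

#' Sample from the wrapped Cauchy distribution
#'
#' Draws are generated by sampling a real-line Cauchy with location `mu`
#' and scale `gamma` and wrapping onto \eqn{[-\pi,\pi)}; this is exact and
#' rejection-free, and reproduces the mean resultant \eqn{e^{i\mu-\gamma}}.
#'
#' @param n Number of draws.
#' @param mu Circular location (radians).
#' @param gamma Scale, strictly positive.
#' @return Numeric vector of `n` wrapped angles.
#' @export
rwcauchy <- function(n, mu = 0, gamma) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be a single finite value > 0", call. = FALSE)
  }
  wrap_angle(stats::rcauchy(n, location = mu, scale = gamma))
}

#' Link chain between wrapped Cauchy scale, circular variance, and the
#' linear predictor
#'
#' The hierarchical model works on three equivalent scales: the wrapped
#' Cauchy scale \eqn{\gamma > 0}, the circular variance
#' \eqn{S = 1 - e^{-\gamma} \in (0,1)}, and the unbounded linear predictor
#' \eqn{\upsilon} with \eqn{S = \mathrm{logistic}(\upsilon)}. The mean
#' resultant length is \eqn{R = 1 - S = e^{-\gamma}}.
#'
#' @param gamma Wrapped Cauchy scale(s), > 0.
#' @param s Circular variance(s) in (0, 1).
#' @param upsilon Linear predictor value(s), finite.
#' @return Numeric vector on the requested scale.
#' @name link-chain
NULL

#' @rdname link-chain
#' @export
s_from_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) == 0L || any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("`gamma` must be finite and > 0", call. = FALSE)
  }
  -expm1(-gamma)
}

#' @rdname link-chain
#' @export
gamma_from_s <- function(s) {
  if (!is.numeric(s) || length(s) == 0L || any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    stop("`s` must lie strictly inside (0, 1)", call. = FALSE)
  }
  -log1p(-s)
}

#' @rdname link-chain
#' @export
s_from_upsilon <- function(upsilon) {
  if (!is.numeric(upsilon) || length(upsilon) == 0L || any(!is.finite(upsilon))) {
    stop("`upsilon` must be finite", call. = FALSE)
  }
  stats::plogis(upsilon)
}
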