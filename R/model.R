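#' Prior configuration
#'
#' Hyperparameters of the hierarchical model's priors.
#'
#' * `s_prior_a`, `s_prior_b`: Beta shape parameters for the baseline
#'   circular variance \eqn{S_c = \mathrm{logistic}(\alpha_c)} of each
#'   condition. The default Beta(5, 2) places most mass above one half,
#'   encoding the expectation that frequency-tagged effects are weak.
#'   Beta(1, 1) recovers a uniform prior on `S` (used by the bias study).
#' * `radial_shape`, `radial_rate`: gamma parameters of the radial profile
#'   of the planar ring ("Bundt") prior on each mean-phase coordinate pair;
#'   the default shape = rate = 100 concentrates the radius near 1 with
#'   standard deviation 0.1. Only the angle is used by the model.
#' * `sigma_beta_scale`, `sigma_delta_scale`: half-normal scales of the
#'   hyperpriors on the participant- and electrode-slope standard
#'   deviations.
#' * `lkj_eta`: shape of the LKJ prior on the across-condition correlation
#'   matrix of participant slopes (default 2, mildly favouring identity).
#' * `nu`: degrees of freedom of the multivariate t on participant slopes;
#'   a number (> 2) fixes it (default 30), the string `"estimate"` gives it
#'   a shifted-gamma prior `nu - 2 ~ Gamma(nu_prior_shape, nu_prior_rate)`.
#'
#' @param s_prior_a,s_prior_b,radial_shape,radial_rate Positive shapes/rates.
#' @param sigma_beta_scale,sigma_delta_scale Positive half-normal scales.
#' @param lkj_eta Positive LKJ shape.
#' @param nu Fixed degrees of freedom (> 2) or `"estimate"`.
#' @param nu_prior_shape,nu_prior_rate Gamma parameters for the `nu` prior
#'   when estimated.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(s_prior_a = 5, s_prior_b = 2,
                         radial_shape = 100, radial_rate = 100,
                         sigma_beta_scale = 1, sigma_delta_scale = 1,
                         lkj_eta = 2, nu = 30,
                         nu_prior_shape = 2, nu_prior_rate = 0.1) {
  pos <- c(s_prior_a, s_prior_b, radial_shape, radial_rate,
           sigma_beta_scale, sigma_delta_scale, lkj_eta,
           nu_prior_shape, nu_prior_rate)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all prior shapes and scales must be finite and > 0", call. = FALSE)
  }
  estimate_nu <- identical(nu, "estimate")
  if (!estimate_nu) {
    if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 2) {
      stop("`nu` must be > 2 or the string \"estimate\"", call. = FALSE)
    }
  }
  structure(list(
    s_prior_a = s_prior_a, s_prior_b = s_prior_b,
    radial_shape = radial_shape, radial_rate = radial_rate,
    sigma_beta_scale = sigma_beta_scale, sigma_delta_scale = sigma_delta_scale,
    lkj_eta = lkj_eta,
    nu = if (estimate_nu) NA_real_ else nu,
    estimate_nu = estimate_nu,
    nu_prior_shape = nu_prior_shape, nu_prior_rate = nu_prior_rate
  ), class = "prior_config")
}

#' Model parameter set
#'
#' The full (centred) parameter vector of the hierarchical model:
#' condition effects `alpha` (length C), participant-by-condition slopes
#' `beta` (P x C), condition-by-electrode slopes `delta` (C x E), planar
#' mean-phase coordinates `mu_xy` (P x C x E x 2), participant-slope
#' scales `sigma_beta` and correlation `corr_beta`, electrode-slope scales
#' `sigma_delta`, and the t degrees of freedom `nu`.
#'
#' @param alpha Numeric length-C condition effects.
#' @param beta P x C matrix of participant slopes.
#' @param delta C x E matrix of electrode slopes.
#' @param mu_xy P x C x E x 2 array of planar coordinates (x, y); the mean
#'   phase of a cell is `atan2(y, x)`.
#' @param sigma_beta,sigma_delta Positive length-C scales.
#' @param corr_beta C x C correlation matrix (symmetric positive definite,
#'   unit diagonal).
#' @param nu Degrees of freedom, > 2.
#' @return An object of class `model_params`.
#' @export
model_params <- function(alpha, beta, delta, mu_xy, sigma_beta, corr_beta,
                         sigma_delta, nu = 30) {
  C <- length(alpha)
  beta <- as.matrix(beta); delta <- as.matrix(delta)
  P <- nrow(beta); E <- ncol(delta)
  if (ncol(beta) != C || nrow(delta) != C) {
    stop("`beta` must be P x C and `delta` C x E", call. = FALSE)
  }
  if (!is.array(mu_xy) || !all(dim(mu_xy) == c(P, C, E, 2))) {
    stop("`mu_xy` must be a P x C x E x 2 array", call. = FALSE)
  }
  if (length(sigma_beta) != C || length(sigma_delta) != C ||
      any(sigma_beta <= 0) || any(sigma_delta <= 0)) {
    stop("`sigma_beta` and `sigma_delta` must be positive length-C", call. = FALSE)
  }
  corr_beta <- as.matrix(corr_beta)
  if (!all(dim(corr_beta) == c(C, C)) ||
      max(abs(corr_beta - t(corr_beta))) > 1e-8 ||
      max(abs(diag(corr_beta) - 1)) > 1e-8) {
    stop("`corr_beta` must be a C x C correlation matrix", call. = FALSE)
  }
  ev <- eigen(corr_beta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`corr_beta` must be positive definite", call. = FALSE)
  if (!is.finite(nu) || nu <= 2) stop("`nu` must be > 2", call. = FALSE)
  rho <- sqrt(mu_xy[, , , 1, drop = FALSE]^2 + mu_xy[, , , 2, drop = FALSE]^2)
  if (any(rho == 0)) stop("`mu_xy` contains a coordinate pair at the origin", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = beta, delta = delta,
                 mu_xy = mu_xy, sigma_beta = as.numeric(sigma_beta),
                 corr_beta = corr_beta, sigma_delta = as.numeric(sigma_delta),
                 nu = nu),
            class = "model_params")
}

#' Mean phase from planar coordinates
#'
#' The circular location used by the likelihood is the angle of the planar
#' coordinate pair, `atan2(y, x)`, wrapped to \eqn{[-\pi, \pi)}.
#'
#' @param x,y Planar coordinates; `(0, 0)` is rejected.
#' @return Angle(s) in \eqn{[-\pi, \pi)}.
#' @export
mu_from_xy <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(x == 0 & y == 0)) {
    stop("the origin has no angle; (x, y) must not be (0, 0)", call. = FALSE)
  }
  wrap_angle(atan2(y, x))
}

#' Log-density of the planar ring ("Bundt") prior
#'
#' A rotation-invariant planar density whose radial profile concentrates
#' the radius \eqn{\rho = \sqrt{x^2+y^2}} near 1: the gamma log-density of
#' \eqn{\rho} is used as the planar log-density increment. Because the
#' density depends on `(x, y)` only through \eqn{\rho}, the implied angle
#' is exactly uniform on the circle, which is the property the model needs
#' (the radius itself is never used). Note that, through the polar-area
#' Jacobian, the implied radial *marginal* is `Gamma(shape + 1, rate)`
#' rather than `Gamma(shape, rate)`; [draw_params_from_prior()] samples
#' accordingly.
#'
#' @param x,y Planar coordinates; `(0, 0)` is rejected.
#' @param cfg A [prior_config()].
#' @return Log-density contribution(s).
#' @export
bundt_logprior <- function(x, y, cfg = prior_config()) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  rho <- sqrt(x^2 + y^2)
  if (any(rho == 0)) stop("(x, y) must not be the origin", call. = FALSE)
  stats::dgamma(rho, shape = cfg$radial_shape, rate = cfg$radial_rate, log = TRUE)
}

#' Linear predictor of the circular variance
#'
#' \eqn{\upsilon_{pce} = \alpha_c + \beta_{pc} + \delta_{ce}}: the additive
#' effect of condition, participant, and electrode on the logit of the
#' circular variance.
#'
#' @param params A [model_params()].
#' @param p,c,e Indices (1-based). Omit all three to obtain the full
#'   `P x C x E` array.
#' @return A scalar, or the full array when indices are omitted.
#' @export
linear_predictor <- function(params, p = NULL, c = NULL, e = NULL) {
  stopifnot(inherits(params, "model_params"))
  P <- nrow(params$beta); C <- length(params$alpha); E <- ncol(params$delta)
  if (is.null(p) && is.null(c) && is.null(e)) {
    ups <- array(0, dim = c(P, C, E))
    for (ci in seq_len(C)) {
      ups[, ci, ] <- params$alpha[ci] + outer(params$beta[, ci], params$delta[ci, ], "+")
    }
    return(ups)
  }
  if (is.null(p) || is.null(c) || is.null(e) ||
      p < 1 || p > P || c < 1 || c > C || e < 1 || e > E) {
    stop("indices (p, c, e) must all be supplied and in range", call. = FALSE)
  }
  params$alpha[c] + params$beta[p, c] + params$delta[c, e]
}

# Per-cell wrapped Cauchy parameters implied by the model.
# Returns list(mu = PxCxE, s = PxCxE). Errors if any S saturates to 0 or 1.
cell_wc_params <- function(params) {
  ups <- linear_predictor(params)
  s <- stats::plogis(ups)
  if (any(s <= 0) || any(s >= 1)) {
    stop("a cell circular variance is numerically 0 or 1; linear predictor out of range",
         call. = FALSE)
  }
  mu <- mu_from_xy(params$mu_xy[, , , 1], params$mu_xy[, , , 2])
  dim(mu) <- dim(s)
  list(mu = mu, s = s)
}

#' Log-likelihood of a phase dataset under the hierarchical model
#'
#' Sums the wrapped Cauchy log-density of every observed trial phase, with
#' per-cell location \eqn{\mu_{pce} = \mathrm{atan2}(y_{pce}, x_{pce})} and
#' scale \eqn{\gamma_{pce} = -\log(1 - S_{pce})},
#' \eqn{S_{pce} = \mathrm{logistic}(\upsilon_{pce})}. Missing trials
#' contribute nothing.
#'
#' @param params A [model_params()].
#' @param data A [phase_dataset()].
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "model_params"), inherits(data, "phase_dataset"))
  cw <- cell_wc_params(params)
  q <- 1 - cw$s                        # e^{-gamma}
  ph <- data$phases
  K <- dim(ph)[4]
  ll <- 0
  for (k in seq_len(K)) {
    th <- ph[, , , k]
    obs <- !is.na(th)
    if (!any(obs)) next
    d <- th[obs] - cw$mu[obs]
    qq <- q[obs]
    ll <- ll + sum(log1p(-qq^2) - log1p(qq^2 - 2 * qq * cos(d)) - log(2 * pi))
  }
  ll
}

# log density of a zero-mean multivariate t with scale matrix Sigma
mvt_logdensity <- function(x, sigma, nu) {
  d <- length(x)
  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  m <- sum(backsolve(ch, x, transpose = TRUE)^2)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    0.5 * logdet - ((nu + d) / 2) * log1p(m / nu)
}

#' Log-prior of the model parameters
#'
#' The joint log prior density in the centred parameterisation:
#' * Beta(`s_prior_a`, `s_prior_b`) on each baseline circular variance
#'   \eqn{S_c = \mathrm{logistic}(\alpha_c)}, including the logit-transform
#'   Jacobian so the density is over \eqn{\alpha_c};
#' * a zero-mean multivariate t (df `nu`, scale
#'   `diag(sigma_beta) corr_beta diag(sigma_beta)`) on each participant's
#'   row of slopes;
#' * Normal(0, `sigma_delta[c]`) on each electrode slope;
#' * the planar ring prior ([bundt_logprior()]) on each coordinate pair;
#' * half-normal hyperpriors on `sigma_beta`, `sigma_delta`;
#' * an LKJ(`lkj_eta`) kernel \eqn{(\eta - 1)\log\det} on `corr_beta`
#'   (evaluated without its normalising constant);
#' * when `cfg` estimates `nu`, a shifted-gamma prior on `nu - 2`.
#'
#' @param params A [model_params()].
#' @param cfg A [prior_config()].
#' @return The scalar log prior (up to the LKJ normalising constant).
#' @export
log_prior <- function(params, cfg = prior_config()) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "prior_config"))
  C <- length(params$alpha)
  # condition effects through the Beta prior on S
  s_c <- stats::plogis(params$alpha)
  lp <- sum(stats::dbeta(s_c, cfg$s_prior_a, cfg$s_prior_b, log = TRUE) +
              log(s_c) + log1p(-s_c))
  # participant slopes: multivariate t rows
  sigma <- diag(params$sigma_beta, C) %*% params$corr_beta %*% diag(params$sigma_beta, C)
  for (p in seq_len(nrow(params$beta))) {
    lp <- lp + mvt_logdensity(params$beta[p, ], sigma, params$nu)
  }
  # electrode slopes
  for (ci in seq_len(C)) {
    lp <- lp + sum(stats::dnorm(params$delta[ci, ], 0, params$sigma_delta[ci], log = TRUE))
  }
  # mean-phase coordinates
  lp <- lp + sum(bundt_logprior(params$mu_xy[, , , 1], params$mu_xy[, , , 2], cfg))
  # hyperpriors
  lp <- lp + sum(stats::dnorm(params$sigma_beta, 0, cfg$sigma_beta_scale, log = TRUE) + log(2))
  lp <- lp + sum(stats::dnorm(params$sigma_delta, 0, cfg$sigma_delta_scale, log = TRUE) + log(2))
  if (C > 1) {
    lp <- lp + (cfg$lkj_eta - 1) * determinant(params$corr_beta, logarithm = TRUE)$modulus[1]
  }
  if (cfg$estimate_nu) {
    lp <- lp + stats::dgamma(params$nu - 2, cfg$nu_prior_shape,
                             rate = cfg$nu_prior_rate, log = TRUE)
  }
  as.numeric(lp)
}

# --- LKJ via the C-vine partial-correlation representation -------------------
# z is the strict lower triangle in row order ((2,1), (3,1), (3,2), ...); the
# entry in column j is the canonical partial correlation of vine layer j and,
# under LKJ(eta), has an independent scaled Beta(b_j, b_j) distribution with
# b_j = eta + (C - 1 - j) / 2.  chol_from_partials() builds the Cholesky
# factor of the correlation matrix from these partials.
chol_from_partials <- function(z, C) {
  L <- diag(1, C)
  idx <- 0L
  for (i in seq_len(C)[-1]) {
    rem <- 1
    for (j in seq_len(i - 1L)) {
      idx <- idx + 1L
      L[i, j] <- z[idx] * sqrt(rem)
      rem <- rem - L[i, j]^2
    }
    L[i, i] <- sqrt(max(rem, 0))
  }
  L
}

rlkj_chol <- function(C, eta) {
  if (C == 1L) return(matrix(1, 1, 1))
  m <- C * (C - 1L) / 2L
  z <- numeric(m)
  idx <- 0L
  for (i in seq_len(C)[-1]) {
    for (j in seq_len(i - 1L)) {
      idx <- idx + 1L
      b <- eta + (C - 1 - j) / 2
      z[idx] <- 2 * stats::rbeta(1, b, b) - 1
    }
  }
  chol_from_partials(z, C)
}

#' Draw a full parameter set from the prior
#'
#' One joint draw of all model parameters under the generative prior,
#' used by forward simulation and simulation-based calibration.
#'
#' @param cfg A [prior_config()].
#' @param layout An [experiment_layout()].
#' @param seed Optional integer seed (uses and restores the global RNG
#'   stream when supplied).
#' @return A [model_params()].
#' @export
draw_params_from_prior <- function(cfg, layout, seed = NULL) {
  stopifnot(inherits(cfg, "prior_config"), inherits(layout, "experiment_layout"))
  if (!is.null(seed)) set.seed(seed)
  P <- layout$n_participants; C <- layout$n_conditions; E <- layout$n_electrodes
  nu <- if (cfg$estimate_nu) {
    2 + stats::rgamma(1, cfg$nu_prior_shape, rate = cfg$nu_prior_rate)
  } else cfg$nu
  s_c <- stats::rbeta(C, cfg$s_prior_a, cfg$s_prior_b)
  alpha <- stats::qlogis(s_c)
  sigma_beta <- abs(stats::rnorm(C, 0, cfg$sigma_beta_scale))
  sigma_delta <- abs(stats::rnorm(C, 0, cfg$sigma_delta_scale))
  L <- rlkj_chol(C, cfg$lkj_eta)
  corr <- L %*% t(L)
  # multivariate t rows: scaled normal over sqrt of a Gamma(nu/2, nu/2) mix
  g <- stats::rgamma(P, nu / 2, rate = nu / 2)
  z <- matrix(stats::rnorm(P * C), P, C)
  beta <- t(diag(sigma_beta, C) %*% L %*% t(z)) / sqrt(g)
  delta <- matrix(stats::rnorm(C * E), C, E) * sigma_delta
  rho <- stats::rgamma(P * C * E, shape = cfg$radial_shape + 1, rate = cfg$radial_rate)
  ang <- stats::runif(P * C * E, -pi, pi)
  mu_xy <- array(c(rho * cos(ang), rho * sin(ang)), dim = c(P, C, E, 2))
  model_params(alpha, beta, delta, mu_xy, sigma_beta, corr, sigma_delta, nu)
}

#' Simulate a phase dataset from the generative model
#'
#' Draws every trial phase independently from the wrapped Cauchy
#' distribution of its cell. In the degenerate mode (an explicit flag) all
#' trials equal the cell mean phase, emulating the \eqn{\gamma \to 0}
#' point-mass limit.
#'
#' @param params A [model_params()].
#' @param layout An [experiment_layout()] matching the parameter dimensions.
#' @param seed Optional integer seed.
#' @param frequency Metadata frequency in Hz.
#' @param degenerate If `TRUE`, emit the zero-dispersion limit.
#' @return A [phase_dataset()].
#' @export
simulate_dataset <- function(params, layout, seed = NULL, frequency = NA_real_,
                             degenerate = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(layout, "experiment_layout"))
  if (!is.null(seed)) set.seed(seed)
  P <- layout$n_participants; C <- layout$n_conditions
  E <- layout$n_electrodes; K <- layout$n_trials
  if (!all(dim(params$beta) == c(P, C)) || !all(dim(params$delta) == c(C, E))) {
    stop("parameter dimensions do not match the layout", call. = FALSE)
  }
  cw <- cell_wc_params(params)
  ph <- array(NA_real_, dim = c(P, C, E, K))
  if (degenerate) {
    for (k in seq_len(K)) ph[, , , k] <- cw$mu
  } else {
    gam <- gamma_from_s(cw$s)
    dim(gam) <- dim(cw$s)
    n_cell <- P * C * E
    draws <- wrap_angle(stats::rcauchy(n_cell * K,
                                       location = rep(as.vector(cw$mu), times = K),
                                       scale = rep(as.vector(gam), times = K)))
    ph <- array(draws, dim = c(P, C, E, K))
  }
  phase_dataset(ph, frequency = frequency, layout = layout)
}
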