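test_that("mean phase from planar coordinates handles the branch cut", {
  expect_equal(mu_from_xy(1, 0), 0)
  expect_equal(mu_from_xy(0, -1), -pi / 2)
  up <- mu_from_xy(-1, 1e-12)
  dn <- mu_from_xy(-1, -1e-12)
  expect_true(up > pi - 1e-6)
  expect_true(dn >= -pi && dn < -pi + 1e-6)
  expect_error(mu_from_xy(0, 0), "origin")
})

test_that("the planar ring prior is rotation invariant with radius near one", {
  cfg <- prior_config()
  set.seed(2)
  x <- stats::rnorm(200); y <- stats::rnorm(200)
  expect_identical(bundt_logprior(x, y, cfg), bundt_logprior(-y, x, cfg))
  th <- 0.83
  expect_equal(bundt_logprior(x, y, cfg),
               bundt_logprior(cos(th) * x - sin(th) * y,
                              sin(th) * x + cos(th) * y, cfg),
               tolerance = 1e-9)
  expect_error(bundt_logprior(0, 0, cfg), "origin")
})

test_that("linear predictor is the additive condition/participant/electrode effect", {
  params <- flat_params(c(0.5, 0.5), P = 3, E = 4)
  expect_equal(linear_predictor(params, 1, 1, 1), 0)
  expect_equal(s_from_upsilon(linear_predictor(params, 2, 2, 3)), 0.5)
  params$alpha <- c(-2, 0)
  expect_equal(linear_predictor(params, 1, 1, 1), -2)
  expect_equal(s_from_upsilon(-2), 0.1192029, tolerance = 1e-6)
  params$beta[2, 1] <- params$beta[2, 1] + 0.7
  expect_equal(linear_predictor(params, 2, 1, 3), -2 + 0.7)
  full <- linear_predictor(params)
  expect_equal(full[2, 1, 3], -1.3)
  expect_error(linear_predictor(params, 1, 1, 99), "range")
})

test_that("log likelihood decomposes into per-trial wrapped Cauchy terms", {
  lay <- experiment_layout(2, 2, 3, 4)
  cfg <- prior_config()
  params <- draw_params_from_prior(cfg, lay, seed = 21)
  data <- simulate_dataset(params, lay, seed = 22)
  data$phases[2, 1, 3, c(1, 4)] <- NA   # missing trials contribute nothing
  ll <- log_likelihood(params, data)
  # independent oracle: explicit loop over cells through the scalar density
  oracle <- 0
  for (p in 1:2) for (ci in 1:2) for (e in 1:3) {
    ups <- linear_predictor(params, p, ci, e)
    g <- gamma_from_s(s_from_upsilon(ups))
    m <- mu_from_xy(params$mu_xy[p, ci, e, 1], params$mu_xy[p, ci, e, 2])
    th <- data$phases[p, ci, e, ]
    th <- th[!is.na(th)]
    oracle <- oracle + sum(dwcauchy(th, m, g, log = TRUE))
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
  # duplicating every trial doubles the log likelihood exactly
  ph2 <- array(NA_real_, dim = c(2, 2, 3, 8))
  ph2[, , , 1:4] <- data$phases; ph2[, , , 5:8] <- data$phases
  lay2 <- experiment_layout(2, 2, 3, 8)
  data2 <- phase_dataset(ph2, layout = lay2)
  expect_equal(log_likelihood(params, data2), 2 * ll, tolerance = 1e-10)
})

test_that("a near-uniform cell gives the uniform log density per phase", {
  lay <- experiment_layout(1, 1, 1, 1)
  s_target <- s_from_gamma(20)
  params <- flat_params(1 - s_target, P = 1, E = 1)
  data <- phase_dataset(array(0.3, dim = c(1, 1, 1, 1)), layout = lay)
  expect_equal(log_likelihood(params, data), -log(2 * pi), tolerance = 1e-6)
})

test_that("log prior reduces to known scalar densities", {
  cfg <- prior_config()
  # C = 1: the multivariate t term is the univariate t density
  lay <- experiment_layout(1, 1, 1, 1)
  params0 <- draw_params_from_prior(cfg, lay, seed = 31)
  pb <- params0
  pb$beta[1, 1] <- 0.6
  params0$beta[1, 1] <- 0
  sigma <- params0$sigma_beta[1]
  t_ref <- stats::dt(0.6 / sigma, df = 30, log = TRUE) -
    stats::dt(0, df = 30, log = TRUE)
  expect_equal(log_prior(pb, cfg) - log_prior(params0, cfg), t_ref,
               tolerance = 1e-10)
  # with a uniform Beta the alpha term is the pure logit Jacobian
  cfg_u <- prior_config(s_prior_a = 1, s_prior_b = 1)
  params0$alpha <- 0
  pa <- params0; pa$alpha <- 1.3
  s <- stats::plogis(1.3)
  expect_equal(log_prior(pa, cfg_u) - log_prior(params0, cfg_u),
               log(s * (1 - s)) - log(0.25), tolerance = 1e-10)
  # global rotation of all coordinate pairs leaves the prior unchanged
  lay2 <- experiment_layout(3, 2, 4, 2)
  p2 <- draw_params_from_prior(cfg, lay2, seed = 32)
  rot <- p2
  th <- 1.1
  rot$mu_xy[, , , 1] <- cos(th) * p2$mu_xy[, , , 1] - sin(th) * p2$mu_xy[, , , 2]
  rot$mu_xy[, , , 2] <- sin(th) * p2$mu_xy[, , , 1] + cos(th) * p2$mu_xy[, , , 2]
  expect_equal(log_prior(rot, cfg), log_prior(p2, cfg), tolerance = 1e-9)
})

test_that("joint density is exchangeable over participants", {
  cfg <- prior_config()
  lay <- experiment_layout(4, 2, 3, 5)
  params <- draw_params_from_prior(cfg, lay, seed = 41)
  data <- simulate_dataset(params, lay, seed = 42)
  perm <- c(3, 1, 4, 2)
  pp <- params
  pp$beta <- params$beta[perm, , drop = FALSE]
  pp$mu_xy <- params$mu_xy[perm, , , , drop = FALSE]
  dp <- data
  dp$phases <- data$phases[perm, , , , drop = FALSE]
  expect_equal(log_likelihood(pp, dp) + log_prior(pp, cfg),
               log_likelihood(params, data) + log_prior(params, cfg),
               tolerance = 1e-9)
})

test_that("forward simulation honours the generative wrapped Cauchy", {
  # degenerate mode: every trial equals the cell mean phase
  lay <- experiment_layout(2, 1, 2, 6)
  params <- flat_params(0.5, P = 2, E = 2)
  dg <- simulate_dataset(params, lay, seed = 1, degenerate = TRUE)
  tab <- itpc_table(dg)
  expect_true(all(abs(tab$values - 1) < 1e-9))
  # a single cell with R = 0.3 and many trials reproduces itpc ~ 0.3
  lay1 <- experiment_layout(1, 1, 1, 1e4)
  p1 <- flat_params(0.3, P = 1, E = 1)
  d1 <- simulate_dataset(p1, lay1, seed = 2)
  expect_equal(itpc(d1$phases[1, 1, 1, ]), 0.3, tolerance = 0.02)
  # determinism
  d2a <- simulate_dataset(p1, lay1, seed = 9)
  d2b <- simulate_dataset(p1, lay1, seed = 9)
  expect_identical(d2a$phases, d2b$phases)
})

test_that("with zero electrode effects, electrode itpc spread is trial noise only", {
  R <- 0.5; E <- 24
  sds <- vapply(c(20, 500), function(K) {
    lay <- experiment_layout(1, 1, E, K)
    d <- simulate_dataset(flat_params(R, P = 1, E = E, seed = K), lay, seed = K + 1)
    stats::sd(itpc_table(d)$values[1, 1, ])
  }, numeric(1))
  expect_gt(sds[1], sds[2])          # variance shrinks as K grows
  expect_lt(sds[2], 0.05)
})

test_that("prior draws follow their generating distributions", {
  cfg <- prior_config()
  lay <- experiment_layout(1, 2, 1, 1)
  set.seed(51)
  n <- 4000
  s_draws <- t(vapply(seq_len(n), function(i) {
    stats::plogis(draw_params_from_prior(cfg, lay)$alpha)
  }, numeric(2)))
  # Beta(5, 2) moments
  expect_equal(mean(s_draws), 5 / 7, tolerance = 0.01)
  expect_lt(abs(stats::var(as.vector(s_draws)) - 5 * 2 / (49 * 8)), 0.004)
  # mean phases uniform on the circle (many cells of one draw)
  lay2 <- experiment_layout(30, 2, 40, 1)
  p2 <- draw_params_from_prior(cfg, lay2, seed = 52)
  ang <- mu_from_xy(as.vector(p2$mu_xy[, , , 1]), as.vector(p2$mu_xy[, , , 2]))
  ks <- stats::ks.test(ang, "punif", -pi, pi)
  expect_gt(ks$p.value, 0.01)
  # radius concentrates near 1
  rho <- sqrt(p2$mu_xy[, , , 1]^2 + p2$mu_xy[, , , 2]^2)
  expect_equal(mean(rho), 1, tolerance = 0.02)
  expect_lt(abs(stats::sd(rho) - 0.1), 0.02)
  # determinism
  expect_identical(draw_params_from_prior(cfg, lay2, seed = 8),
                   draw_params_from_prior(cfg, lay2, seed = 8))
})

test_that("prior predictive cell coherence concentrates below one half", {
  cfg <- prior_config()
  lay <- experiment_layout(6, 2, 8, 1)
  set.seed(61)
  frac_below <- mean(vapply(1:200, function(i) {
    p <- draw_params_from_prior(cfg, lay)
    r_cell <- 1 - s_from_upsilon(linear_predictor(p))
    mean(r_cell < 0.5)
  }, numeric(1)))
  expect_gt(frac_below, 0.6)
})
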