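test_that("seeded sampling is exactly reproducible", {
  data <- simulate_flat(c(0.4, 0.2), P = 3, E = 3, K = 8, seed = 1)
  f1 <- quick_fit(data, seed = 7, iterations = 200)
  f2 <- quick_fit(data, seed = 7, iterations = 200)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$energy, f2$energy)
  f3 <- quick_fit(data, seed = 8, iterations = 200)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("sampler requires at least two chains", {
  data <- simulate_flat(0.4, P = 2, E = 2, K = 5, seed = 2)
  expect_error(sample_posterior(data, chains = 1, iterations = 100), "2 chains")
})

test_that("prior-only sampling recovers the Beta prior on circular variance", {
  data <- simulate_flat(c(0.4, 0.2), P = 4, E = 4, K = 8, seed = 3)
  cfg <- prior_config()
  fit <- sample_posterior(data, cfg, chains = 2, iterations = 1200, seed = 5,
                          prior_only = TRUE)
  s <- stats::plogis(as.vector(fit$params[, "alpha[cond1]", ]))
  ess <- effective_sample_size(stats::plogis(fit$params[, "alpha[cond1]", ]))
  expect_lt(abs(mean(s) - 5 / 7), 4 * sqrt(10 / (49 * 8)) / sqrt(ess))
  expect_lt(abs(stats::var(s) - 10 / (49 * 8)), 0.012)
  # sigma_beta half-normal(1): mean sqrt(2/pi)
  sb <- as.vector(fit$params[, "sigma_beta[cond2]", ])
  expect_equal(mean(sb), sqrt(2 / pi), tolerance = 0.1)
})

test_that("single-cell posterior matches a dense-grid numerical posterior", {
  # one participant, condition, electrode: derived gamma is identified and a
  # 2-d (alpha, mu) grid posterior is an independent oracle.  The hierarchy
  # is switched off through vanishing slope-scale hyperpriors.
  set.seed(13)
  K <- 30
  th <- rwcauchy(K, mu = 0.8, gamma = 0.7)
  data <- phase_dataset(array(th, dim = c(1, 1, 1, K)))
  cfg <- prior_config(sigma_beta_scale = 1e-6, sigma_delta_scale = 1e-6)
  fit <- sample_posterior(data, cfg, chains = 2, iterations = 3000, seed = 17)
  ups_draws <- as.vector(fit$params[, "alpha[cond1]", ]) +
    as.vector(fit$params[, "beta[1,cond1]", ]) +
    as.vector(fit$params[, "delta[cond1,1]", ])
  g_draws <- gamma_from_s(s_from_upsilon(ups_draws))

  a_grid <- seq(-5, 5, length.out = 1200)
  m_grid <- seq(-pi, pi, length.out = 400)
  s_grid <- stats::plogis(a_grid)
  lp_a <- 5 * log(s_grid) + 2 * log1p(-s_grid)     # Beta(5,2) with Jacobian
  g_grid <- gamma_from_s(s_grid)
  ll <- outer(seq_along(a_grid), seq_along(m_grid), function(i, j) {
    vapply(seq_along(i), function(t) {
      sum(dwcauchy(th, m_grid[j[t]], g_grid[i[t]], log = TRUE))
    }, numeric(1))
  })
  lj <- ll + lp_a
  w <- exp(lj - max(lj))
  w <- w / sum(w)
  wa <- rowSums(w)
  mean_g <- sum(wa * g_grid)
  sd_g <- sqrt(sum(wa * (g_grid - mean_g)^2))

  ess <- effective_sample_size(matrix(g_draws, ncol = 2))
  mc_se <- stats::sd(g_draws) / sqrt(ess)
  expect_lt(abs(mean(g_draws) - mean_g), 4 * mc_se + 0.01)
  expect_lt(abs(stats::sd(g_draws) - sd_g), 0.05 * sd_g + 4 * mc_se)
})

test_that("fits on a clean fixture converge with no divergences", {
  data <- simulate_flat(c(0.45, 0.15), P = 6, E = 6, K = 16, seed = 23)
  fit <- quick_fit(data, seed = 29, iterations = 800)
  dg <- diagnostics(fit)
  expect_lt(dg$max_rhat, 1.05)
  expect_equal(dg$divergence_count, 0)
  expect_true(all(dg$ebfmi > 0.3))
  # the stronger condition is identified as such
  r1 <- condition_resultant(fit, "cond1")
  r2 <- condition_resultant(fit, "cond2")
  expect_gt(mean(r1), mean(r2))
  expect_true(all(r1 > 0 & r1 < 1) && all(r2 > 0 & r2 < 1))
})

test_that("MAP estimation is consistent and stable across starts", {
  data <- simulate_flat(0.5, P = 1, E = 6, K = 150, seed = 31)
  # slope scales matched to the (zero-effect) generator: with loose slope
  # hyperpriors the joint mode of a hierarchy lets slopes compensate the
  # intercept, a known property of penalised modes
  cfg <- prior_config(sigma_beta_scale = 0.1, sigma_delta_scale = 0.1)
  est <- map_estimate(data, cfg, n_starts = 5, seed = 1)
  expect_lt(abs(est$R[[1]] - 0.5), 0.05)
  est2 <- map_estimate(data, cfg, n_starts = 5, seed = 2)
  expect_lt(abs(est$R[[1]] - est2$R[[1]]), 0.02)
  # degenerate single-trial data: the prior regularises, no crash
  tiny <- phase_dataset(array(0.4, dim = c(1, 1, 1, 1)))
  est3 <- map_estimate(tiny, n_starts = 2, seed = 3)
  expect_true(is.finite(est3$R[[1]]))
  expect_true(est3$R[[1]] > 0 && est3$R[[1]] < 1)
})

test_that("map_trace returns one point estimate per frequency and condition", {
  sets <- lapply(c(1, 2), function(f) {
    d <- simulate_flat(c(0.4, 0.3), P = 2, E = 3, K = 10, seed = f)
    d$frequency <- f
    d
  })
  tr <- map_trace(sets, n_starts = 2, seed = 1)
  expect_equal(nrow(tr), 4)
  expect_setequal(unique(tr$frequency), c(1, 2))
  expect_true(all(tr$R > 0 & tr$R < 1))
})

test_that("condition contrasts follow their defining algebra", {
  lay <- experiment_layout(2, 2, 2, 4, condition_labels = c("A", "B"))
  n <- 400
  set.seed(43)
  a1 <- stats::rnorm(n, -1, 0.3); a2 <- stats::rnorm(n, 0.5, 0.3)
  d_a1e1 <- stats::rnorm(n, 0, 0.1); d_a2e1 <- stats::rnorm(n, -0.8, 0.2)
  pd <- cbind(
    "alpha[A]" = a1, "alpha[B]" = a2,
    "R[A]" = stats::plogis(-a1), "R[B]" = stats::plogis(-a2),
    "delta[A,1]" = d_a1e1, "delta[B,1]" = d_a2e1,
    "delta[A,2]" = 0, "delta[B,2]" = 0)
  fit <- fake_fit(pd, lay)
  expect_equal(condition_resultant(fit, "A"), stats::plogis(-a1))
  cd <- condition_difference(fit, "A", "B")
  expect_equal(cd$draws, stats::plogis(-a1) - stats::plogis(-a2))
  expect_equal(cd$summary$p_gt0, mean(cd$draws > 0))
  expect_equal(cd$summary$p_gt0, 1 - stats::ecdf(cd$draws)(0))
  expect_error(condition_difference(fit, "A", "A"), "different")
  # with zero electrode slopes the electrode contrast nests the condition one
  e2 <- electrode_difference(fit, "A", "B", 2)
  expect_equal(e2$draws, cd$draws)
  # antisymmetry
  e1 <- electrode_difference(fit, "A", "B", 1)
  e1r <- electrode_difference(fit, "B", "A", 1)
  expect_equal(e1$draws, -e1r$draws)
  tab <- electrode_difference_table(fit, "A", "B")
  expect_equal(nrow(tab), 2)
  expect_true(all(abs(cd$draws) < 1))
})

test_that("a planted single-electrode effect is flagged at that electrode", {
  # delta offset -1 in condition 1 at electrode 1 lowers S there -> higher R
  set.seed(53)
  flagged <- matrix(NA, 6, 2)
  for (r in 1:6) {
    lay <- experiment_layout(8, 2, 4, 20)
    params <- flat_params(c(0.35, 0.35), P = 8, E = 4, seed = 100 + r)
    params$delta[1, 1] <- -1
    data <- simulate_dataset(params, lay, seed = 200 + r)
    fit <- quick_fit(data, seed = 300 + r, iterations = 600)
    flagged[r, 1] <- electrode_difference(fit, 1, 2, 1)$flagged
    flagged[r, 2] <- electrode_difference(fit, 1, 2, 3)$flagged
  }
  expect_gte(sum(flagged[, 1]), 5)   # planted electrode detected
  expect_lte(sum(flagged[, 2]), 1)   # clean electrode not flagged
})
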