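test_that("the bias study produces seeded, well-formed records", {
  res <- run_bias_study(n_datasets = 6, seed = 5, chains = 2, iterations = 400)
  expect_equal(nrow(res), 6)
  expect_true(all(res$true_R1 >= 0 & res$true_R1 <= 1))
  expect_true(all(is.finite(res$bayes_ratio)))
  expect_type(res$itpc_detected, "logical")
  res2 <- run_bias_study(n_datasets = 6, seed = 5, chains = 2, iterations = 400)
  expect_identical(res, res2)
})

test_that("large true differences are estimated near ratio one by both arms", {
  set.seed(11)
  # construct replicates with |R1 - R2| > 0.6 directly
  rows <- lapply(1:8, function(i) {
    R <- sort(stats::runif(2, 0, 1))
    R <- c(R[2] * 0.2, 0.75 + 0.2 * R[1])   # guarantees a large gap
    lay <- experiment_layout(5, 2, 8, 10)
    cfg <- prior_config(s_prior_a = 1, s_prior_b = 1)
    set.seed(100 + i)
    params <- draw_params_from_prior(cfg, lay)
    params$alpha <- stats::qlogis(1 - rev(R))
    data <- simulate_dataset(params, lay)
    fit <- sample_posterior(data, cfg, chains = 2, iterations = 500, seed = i)
    cd <- condition_difference(fit, 1, 2)
    (cd$summary$median) / (rev(R)[1] - rev(R)[2])
  })
  ratios <- unlist(rows)
  expect_lt(abs(mean(ratios) - 1), 0.2)
  expect_true(all(ratios > 0.5 & ratios < 1.5))
})

test_that("sbc ranks are bounded and reproducible", {
  sbc <- run_sbc(layout = experiment_layout(3, 2, 3, 6), n_sims = 10,
                 rank_draws = 20, seed = 3, chains = 2, iterations = 300)
  expect_true(all(sbc$ranks >= 0 & sbc$ranks <= 20))
  expect_equal(length(sbc$ranks) + sbc$n_failed, 10)
  sbc2 <- run_sbc(layout = experiment_layout(3, 2, 3, 6), n_sims = 10,
                  rank_draws = 20, seed = 3, chains = 2, iterations = 300)
  expect_identical(sbc$ranks, sbc2$ranks)
})

test_that("the ecdf band is itself calibrated and flags gross violations", {
  set.seed(7)
  L <- 50
  # uniform synthetic ranks: the 95% band is exited ~5% of the time
  flags <- vapply(1:300, function(i) {
    r <- sample.int(L + 1, 150, replace = TRUE) - 1L
    ecdf_band(r, coverage = 0.95, n_mc = 400, L = L, seed = i)$violated
  }, logical(1))
  expect_lt(abs(mean(flags) - 0.05), 0.04)
  # a point mass is an extreme violation
  eb_bad <- ecdf_band(rep(12L, 150), coverage = 0.99, n_mc = 400, L = L)
  expect_true(eb_bad$violated)
  # the band shrinks as the number of simulations grows
  b_small <- ecdf_band(sample.int(L + 1, 80, TRUE) - 1L, coverage = 0.99,
                       n_mc = 800, L = L)$band
  b_large <- ecdf_band(sample.int(L + 1, 800, TRUE) - 1L, coverage = 0.99,
                       n_mc = 800, L = L)$band
  expect_gt(b_small, b_large)
})

test_that("efficiency curves agree with direct fits on the full data", {
  data <- simulate_flat(c(0.5, 0.3), P = 6, E = 4, K = 12, seed = 21)
  curve <- participant_efficiency_curve(data, 1, 2, min_participants = 5,
                                        chains = 2, iterations = 500, seed = 9)
  expect_equal(nrow(curve), 2)          # P = 6 and P = 5
  expect_equal(curve$n_participants, c(6, 5))
  full <- curve[1, ]
  # the full-data row equals an independent direct computation
  fit <- sample_posterior(data, prior_config(), chains = 2, iterations = 500,
                          seed = 9 + 6)
  cd <- condition_difference(fit, 1, 2, mass = 0.95)
  expect_equal(full$bayes_median, cd$summary$median, tolerance = 1e-12)
  tabw <- itpc_table(data)
  w <- wilcoxon_signed_rank(tabw$electrode_mean[, 1] - tabw$electrode_mean[, 2])
  expect_equal(full$wilcoxon_p, w$p_value, tolerance = 1e-12)
  # trial curve: the full-trial row matches, widths shrink with more trials
  tc <- trial_efficiency_curve(data, 1, 2, trial_grid = c(12, 6),
                               chains = 2, iterations = 500, seed = 30)
  expect_equal(tc$n_trials, c(12, 6))
  w12 <- tc$hdi_high[1] - tc$hdi_low[1]
  w6 <- tc$hdi_high[2] - tc$hdi_low[2]
  expect_lt(w12, w6)
  expect_error(trial_efficiency_curve(data, 1, 2, trial_grid = 99), "exceeds")
})

test_that("removing a strong responder weakens the evidence more than a weak one", {
  # participant effects beta control attentiveness: more negative beta ->
  # lower circular variance -> stronger response
  lay <- experiment_layout(8, 2, 6, 16)
  params <- flat_params(c(0.45, 0.45), P = 8, E = 6, seed = 31)
  params$alpha[2] <- stats::qlogis(1 - 0.2)     # condition 2 weaker overall
  params$beta[7, ] <- c(-1.2, 0)                # participant 7: strong in cond 1
  params$beta[8, ] <- c(0.8, 0)                 # participant 8: weak in cond 1
  data <- simulate_dataset(params, lay, seed = 32)
  drop_p <- function(keep) {
    d <- data
    d$phases <- data$phases[keep, , , , drop = FALSE]
    lay2 <- experiment_layout(length(keep), 2, 6, 16)
    d2 <- phase_dataset(d$phases, layout = lay2)
    fit <- sample_posterior(d2, prior_config(), chains = 2, iterations = 600,
                            seed = 33)
    mean(condition_difference(fit, 1, 2)$draws > 0)
  }
  p_without_strong <- drop_p(c(1:6, 8))
  p_without_weak <- drop_p(c(1:7))
  expect_gt(p_without_weak, p_without_strong)
})
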