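# Validation experiments: estimation-bias study, simulation-based
# calibration, and data-efficiency curves.

#' Estimation-bias simulation study
#'
#' For each replicate, two ground-truth mean resultant lengths
#' \eqn{R_1, R_2} are drawn uniformly on (0, 1) (the Beta prior on the
#' baseline circular variance replaced by a uniform), a two-condition
#' dataset is simulated from the generative model, and the condition
#' difference \eqn{\Delta R = R_1 - R_2} is estimated two ways:
#'
#' * ITPC arm: cell-level ITPC averaged over electrodes then participants
#'   per condition, differenced; detection = paired two-sided Wilcoxon
#'   signed-rank p < 0.05 on the per-participant electrode-averaged ITPC.
#' * Bayesian arm: posterior median of \eqn{\Delta R} under the same
#'   (uniform-baseline) model; detection = zero outside the 95% HDI.
#'
#' Each arm's quality is recorded as the ratio of estimated to true
#' difference (1 = unbiased).
#'
#' @param n_datasets Number of replicates.
#' @param layout An [experiment_layout()] with 2 conditions (default:
#'   5 participants, 10 trials, 8 electrodes).
#' @param seed Integer seed.
#' @param chains,iterations Sampler settings per replicate fit.
#' @return A data.frame, one row per replicate: `true_R1`, `true_R2`,
#'   `itpc_ratio`, `bayes_ratio`, `itpc_detected`, `bayes_detected`,
#'   `seed`.
#' @export
run_bias_study <- function(n_datasets = 100,
                           layout = experiment_layout(5, 2, 8, 10),
                           seed = 1, chains = 2, iterations = 800) {
  stopifnot(n_datasets >= 1, layout$n_conditions == 2)
  cfg <- prior_config(s_prior_a = 1, s_prior_b = 1)  # uniform baseline
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    rep_seed <- seed + i
    set.seed(rep_seed)
    params <- draw_params_from_prior(cfg, layout)
    # overwrite the baseline draw: R_c ~ Uniform(0,1) <=> S_c ~ Uniform(0,1)
    R_true <- stats::runif(2)
    params$alpha <- stats::qlogis(1 - R_true)
    data <- simulate_dataset(params, layout)
    d_true <- R_true[1] - R_true[2]

    tab <- itpc_table(data)
    itpc_est <- mean(tab$electrode_mean[, 1]) - mean(tab$electrode_mean[, 2])
    w <- wilcoxon_signed_rank(tab$electrode_mean[, 1], tab$electrode_mean[, 2])

    fit <- sample_posterior(data, cfg, chains = chains,
                            iterations = iterations, seed = rep_seed)
    cd <- condition_difference(fit, 1, 2, mass = 0.95)
    h <- hdi(cd$draws, 0.95)

    rows[[i]] <- data.frame(
      true_R1 = R_true[1], true_R2 = R_true[2],
      itpc_ratio = if (d_true != 0) itpc_est / d_true else NA_real_,
      bayes_ratio = if (d_true != 0) cd$summary$median / d_true else NA_real_,
      itpc_detected = w$p_value < 0.05,
      bayes_detected = h[["lower"]] > 0 || h[["upper"]] < 0,
      seed = rep_seed)
  }
  do.call(rbind, rows)
}

#' Simulation-based calibration
#'
#' Draws parameters from the prior, simulates a dataset, fits the
#' posterior, and records the rank of the true condition difference
#' \eqn{\Delta R = R_1 - R_2} among `rank_draws` thinned posterior draws.
#' Under a correct model/sampler pair the ranks are uniform on
#' `{0, ..., rank_draws}`. Setting `gamma_scale != 1` corrupts the fitted
#' likelihood (the wrapped Cauchy scale is multiplied by it) and serves
#' as a negative control that should break uniformity.
#'
#' @param cfg A [prior_config()].
#' @param layout An [experiment_layout()] with 2 conditions (default:
#'   the bias-study layout, 5 participants x 10 trials x 8 electrodes).
#' @param n_sims Number of simulations (>= 50 recommended).
#' @param rank_draws Thinned posterior draws per simulation (the rank is
#'   in `{0, ..., rank_draws}`).
#' @param seed Integer seed.
#' @param chains,iterations Sampler settings per fit.
#' @param gamma_scale Likelihood corruption factor (1 = correct model).
#' @return A list of class `sbc_result`: integer `ranks`, `L`
#'   (= `rank_draws`), `n_sims`, and `n_failed`.
#' @export
run_sbc <- function(cfg = prior_config(),
                    layout = experiment_layout(5, 2, 8, 10),
                    n_sims = 200, rank_draws = 50, seed = 1,
                    chains = 2, iterations = 500, gamma_scale = 1) {
  stopifnot(layout$n_conditions == 2)
  ranks <- integer(0)
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    sim_seed <- seed + i
    set.seed(sim_seed)
    params <- draw_params_from_prior(cfg, layout)
    truth <- stats::plogis(-params$alpha[1]) - stats::plogis(-params$alpha[2])
    data <- simulate_dataset(params, layout)
    fit <- tryCatch(
      sample_posterior(data, cfg, chains = chains, iterations = iterations,
                       seed = sim_seed, gamma_scale = gamma_scale),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    draws <- condition_difference(fit, 1, 2)$draws
    keep <- round(seq(1, length(draws), length.out = rank_draws))
    thinned <- draws[keep]
    ranks <- c(ranks, sum(thinned < truth))
  }
  structure(list(ranks = ranks, L = rank_draws, n_sims = n_sims,
                 n_failed = n_failed),
            class = "sbc_result")
}

#' @export
print.sbc_result <- function(x, ...) {
  cat(sprintf("<sbc_result> %d ranks over {0..%d} (%d failed fits)\n",
              length(x$ranks), x$L, x$n_failed))
  invisible(x)
}

#' Simultaneous ECDF band for SBC ranks
#'
#' The difference between the empirical CDF of the observed ranks and the
#' uniform CDF, together with a simultaneous variability band at the
#' requested coverage, computed by Monte Carlo over uniform rank sets of
#' the same size (quantile of the maximal absolute ECDF difference). The
#' violation flag is `TRUE` when the observed difference exits the band
#' anywhere.
#'
#' @param sbc An `sbc_result` (or an integer vector of ranks with
#'   attribute-free `L` supplied).
#' @param coverage Band coverage (default 0.99).
#' @param n_mc Monte Carlo replicates for the band.
#' @param L Maximum rank; taken from `sbc` when it is an `sbc_result`.
#' @param seed Seed for the band's Monte Carlo.
#' @return A list: `rank_grid`, `ecdf_diff`, `band` (half-width),
#'   `violated`.
#' @export
ecdf_band <- function(sbc, coverage = 0.99, n_mc = 2000, L = NULL, seed = 1) {
  if (inherits(sbc, "sbc_result")) { ranks <- sbc$ranks; L <- sbc$L }
  else { ranks <- as.integer(sbc); if (is.null(L)) L <- max(ranks) }
  n <- length(ranks)
  if (n < 1) stop("no ranks supplied", call. = FALSE)
  grid <- 0:L
  unif_cdf <- (grid + 1) / (L + 1)
  obs_cdf <- vapply(grid, function(g) mean(ranks <= g), numeric(1))
  diff_obs <- obs_cdf - unif_cdf
  set.seed(seed)
  max_dev <- numeric(n_mc)
  for (b in seq_len(n_mc)) {
    r <- sample.int(L + 1, n, replace = TRUE) - 1L
    cdf <- cumsum(tabulate(r + 1L, nbins = L + 1L)) / n
    max_dev[b] <- max(abs(cdf - unif_cdf))
  }
  band <- stats::quantile(max_dev, coverage, names = FALSE)
  list(rank_grid = grid, ecdf_diff = diff_obs, band = band,
       violated = any(abs(diff_obs) > band))
}

#' Chi-square uniformity test of SBC ranks
#'
#' Ranks are pooled into `bins` equal-width bins over `{0, ..., L}` and
#' tested against uniformity with [stats::chisq.test()].
#'
#' @param sbc An `sbc_result`.
#' @param bins Number of bins (default 10; keeps expected counts healthy).
#' @return The chi-square p-value.
#' @export
sbc_uniformity_test <- function(sbc, bins = 10) {
  stopifnot(inherits(sbc, "sbc_result"))
  br <- seq(-0.5, sbc$L + 0.5, length.out = bins + 1)
  counts <- table(cut(sbc$ranks, breaks = br))
  stats::chisq.test(as.vector(counts))$p.value
}

# shared engine for the two efficiency curves
efficiency_row <- function(data, c1, c2, cfg, chains, iterations, seed,
                           hdi_mass, conf_level) {
  tab <- itpc_table(data)
  i1 <- resolve_condition_itpc(tab, c1); i2 <- resolve_condition_itpc(tab, c2)
  d <- tab$electrode_mean[, i1] - tab$electrode_mean[, i2]
  w <- if (sum(d != 0, na.rm = TRUE) >= 5) {
    wilcoxon_signed_rank(d, conf_level = conf_level)
  } else NULL
  fit <- sample_posterior(data, cfg, chains = chains,
                          iterations = iterations, seed = seed)
  cd <- condition_difference(fit, c1, c2, mass = hdi_mass)
  data.frame(
    n_participants = data$layout$n_participants,
    n_trials = data$layout$n_trials,
    wilcoxon_p = if (is.null(w)) NA_real_ else w$p_value,
    wilcoxon_low = if (is.null(w)) NA_real_ else w$conf_int[1],
    wilcoxon_high = if (is.null(w)) NA_real_ else w$conf_int[2],
    bayes_median = cd$summary$median,
    hdi_low = cd$summary$hdi_low,
    hdi_high = cd$summary$hdi_high,
    p_delta_lt0 = mean(cd$draws < 0))
}

#' Participant data-efficiency curve
#'
#' Repeats the frequentist (Wilcoxon CI and p on electrode-averaged ITPC
#' differences) and Bayesian (HDI and \eqn{P(\Delta R < 0)}) condition
#' comparisons while participants are removed from the end of the
#' recording order, emulating an experiment stopped early.
#'
#' @param data A [phase_dataset()].
#' @param c1,c2 Conditions to compare.
#' @param min_participants Smallest participant count to analyse.
#' @param cfg A [prior_config()] (the default fixes `nu = 30`, which
#'   stabilises fits at small participant numbers).
#' @param chains,iterations Sampler settings per fit.
#' @param seed Integer seed.
#' @param hdi_mass HDI mass for the Bayesian interval.
#' @param conf_level Wilcoxon confidence level.
#' @return A tidy data.frame, one row per participant count (Wilcoxon
#'   columns `NA` below 5 usable participants).
#' @export
participant_efficiency_curve <- function(data, c1, c2, min_participants = 5,
                                         cfg = prior_config(), chains = 2,
                                         iterations = 1000, seed = 1,
                                         hdi_mass = 0.95, conf_level = 0.95) {
  stopifnot(inherits(data, "phase_dataset"))
  P <- data$layout$n_participants
  rows <- lapply(seq(P, max(min_participants, 2)), function(p) {
    efficiency_row(subset_phases(data, participants = p), c1, c2, cfg,
                   chains, iterations, seed + p, hdi_mass, conf_level)
  })
  do.call(rbind, rows)
}

#' Trial data-efficiency curve
#'
#' As [participant_efficiency_curve()], but discarding trials from the
#' end at a fixed participant count.
#'
#' @inheritParams participant_efficiency_curve
#' @param trial_grid Trial counts to analyse (each <= the available K).
#' @return A tidy data.frame, one row per trial count.
#' @export
trial_efficiency_curve <- function(data, c1, c2, trial_grid,
                                   cfg = prior_config(), chains = 2,
                                   iterations = 1000, seed = 1,
                                   hdi_mass = 0.95, conf_level = 0.95) {
  stopifnot(inherits(data, "phase_dataset"))
  if (any(trial_grid > data$layout$n_trials) || any(trial_grid < 1)) {
    stop("`trial_grid` exceeds the available trials", call. = FALSE)
  }
  rows <- lapply(sort(trial_grid, decreasing = TRUE), function(k) {
    efficiency_row(subset_phases(data, trials = k), c1, c2, cfg,
                   chains, iterations, seed + k, hdi_mass, conf_level)
  })
  do.call(rbind, rows)
}
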