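# Shared fixtures: all synthetic, built in code at test time.

# Parameters with known condition-level mean resultant lengths and no
# participant/electrode effects (so cell-level R equals condition-level R).
flat_params <- function(R_true, P, E, seed = 1) {
  set.seed(seed)
  C <- length(R_true)
  n_cells <- P * C * E
  ang <- stats::runif(n_cells, -pi, pi)
  mu_xy <- array(c(cos(ang), sin(ang)), dim = c(P, C, E, 2))
  model_params(
    alpha = stats::qlogis(1 - R_true),
    beta = matrix(0, P, C),
    delta = matrix(0, C, E),
    mu_xy = mu_xy,
    sigma_beta = rep(0.5, C), corr_beta = diag(C),
    sigma_delta = rep(0.5, C), nu = 30
  )
}

# Two-condition dataset with known R per condition and no cell effects.
simulate_flat <- function(R_true, P, E, K, seed = 1) {
  lay <- experiment_layout(P, length(R_true), E, K)
  params <- flat_params(R_true, P, E, seed = seed)
  simulate_dataset(params, lay, seed = seed + 1)
}

# Small-but-real posterior fit settings used across tests.
quick_fit <- function(data, cfg = prior_config(), seed = 1, iterations = 600) {
  sample_posterior(data, cfg, chains = 2, iterations = iterations, seed = seed)
}

# A synthetic wc_fit whose transformed parameter draws are set directly;
# used to test contrast algebra independently of the sampler.
fake_fit <- function(param_draws, layout) {
  n <- nrow(param_draws)
  arr <- array(param_draws, dim = c(n, ncol(param_draws), 1),
               dimnames = list(NULL, colnames(param_draws), NULL))
  structure(list(params = arr, layout = layout,
                 energy = matrix(stats::rnorm(n), n, 1),
                 divergent = matrix(FALSE, n, 1)),
            class = "wc_fit")
}
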