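# --- bridging between R objects and the C++ density/sampler -----------------

# Flatten a phase_dataset + prior_config into the list the C++ code consumes.
# Observations are sorted by cell (cell index m = p + P*(c-1) + P*C*(e-1)),
# with cell_start giving 0-based offsets per cell.
model_data_list <- function(data, cfg, gamma_scale = 1, prior_only = FALSE) {
  stopifnot(inherits(data, "phase_dataset"), inherits(cfg, "prior_config"))
  lay <- data$layout
  P <- lay$n_participants; C <- lay$n_conditions; E <- lay$n_electrodes
  ph <- data$phases
  n_cells <- P * C * E
  idx <- which(!is.na(ph))
  cell <- ((idx - 1L) %% n_cells) + 1L
  ord <- order(cell)
  th <- ph[idx[ord]]
  counts <- tabulate(cell, nbins = n_cells)
  list(P = P, C = C, E = E,
       cth = cos(th), sth = sin(th),
       cell_start = as.integer(c(0L, cumsum(counts))),
       a = cfg$s_prior_a, b = cfg$s_prior_b,
       rshape = cfg$radial_shape, rrate = cfg$radial_rate,
       sb_scale = cfg$sigma_beta_scale, sd_scale = cfg$sigma_delta_scale,
       eta = cfg$lkj_eta,
       nu = if (cfg$estimate_nu) -1 else cfg$nu,
       estimate_nu = cfg$estimate_nu,
       nu_a = cfg$nu_prior_shape, nu_b = cfg$nu_prior_rate,
       gamma_scale = gamma_scale, prior_only = prior_only)
}

# dimension bookkeeping shared by init / unpack / transform
dim_info <- function(P, C, E, estimate_nu) {
  m_corr <- C * (C - 1L) / 2L
  n_cells <- P * C * E
  o <- list(P = P, C = C, E = E, n_cells = n_cells, m_corr = m_corr,
            estimate_nu = estimate_nu)
  o$alpha <- 1L
  o$zbeta <- o$alpha + C
  o$ug <- o$zbeta + P * C
  o$zdelta <- o$ug + P
  o$xy <- o$zdelta + C * E
  o$lsb <- o$xy + 2L * n_cells
  o$lsd <- o$lsb + C
  o$zc <- o$lsd + C
  o$lnu <- o$zc + m_corr
  o$D <- o$lnu - 1L + (if (estimate_nu) 1L else 0L)
  o
}

random_init <- function(di) {
  q <- numeric(di$D)
  q[di$alpha:(di$zbeta - 1L)] <- stats::rnorm(di$C, 0, 0.5)
  q[di$zbeta:(di$ug - 1L)] <- stats::rnorm(di$P * di$C, 0, 0.2)
  q[di$ug:(di$zdelta - 1L)] <- stats::rnorm(di$P, 0, 0.2)
  q[di$zdelta:(di$xy - 1L)] <- stats::rnorm(di$C * di$E, 0, 0.2)
  ang <- stats::runif(di$n_cells, -pi, pi)
  xy <- rbind(cos(ang), sin(ang))
  q[di$xy:(di$lsb - 1L)] <- as.vector(xy)
  q[di$lsb:(di$lsd - 1L)] <- stats::rnorm(di$C, log(0.5), 0.3)
  q[di$lsd:(di$zc - 1L)] <- stats::rnorm(di$C, log(0.5), 0.3)
  if (di$m_corr > 0) q[di$zc:(di$lnu - 1L)] <- stats::rnorm(di$m_corr, 0, 0.2)
  if (di$estimate_nu) q[di$lnu] <- log(28) + stats::rnorm(1, 0, 0.2)
  q
}

# unconstrained vector -> centred model_params
unpack_params <- function(q, di, cfg) {
  C <- di$C; P <- di$P; E <- di$E
  alpha <- q[di$alpha:(di$zbeta - 1L)]
  zbeta <- matrix(q[di$zbeta:(di$ug - 1L)], P, C)
  g <- exp(q[di$ug:(di$zdelta - 1L)])
  zdelta <- matrix(q[di$zdelta:(di$xy - 1L)], C, E)
  xy <- q[di$xy:(di$lsb - 1L)]
  sb <- exp(q[di$lsb:(di$lsd - 1L)])
  sd_ <- exp(q[di$lsd:(di$zc - 1L)])
  z <- if (di$m_corr > 0) tanh(q[di$zc:(di$lnu - 1L)]) else numeric(0)
  L <- chol_from_partials(z, C)
  nu <- if (di$estimate_nu) 2 + exp(q[di$lnu]) else cfg$nu
  beta <- t(diag(sb, C) %*% L %*% t(zbeta)) / sqrt(g)
  delta <- zdelta * sd_
  mu_xy <- array(0, dim = c(P, C, E, 2))
  xm <- matrix(xy, nrow = 2)          # row 1 = x, row 2 = y, cell-major
  mu_xy[, , , 1] <- array(xm[1, ], dim = c(P, C, E))
  mu_xy[, , , 2] <- array(xm[2, ], dim = c(P, C, E))
  model_params(alpha, beta, delta, mu_xy, sb, L %*% t(L), sd_, nu)
}

# vectorised transform of an (iter x D) unconstrained draw matrix into the
# named core quantities used for summaries and diagnostics
transform_draws <- function(draws, di, cfg, lay) {
  n <- nrow(draws); C <- di$C; P <- di$P; E <- di$E
  cl <- lay$condition_labels
  alpha <- draws[, di$alpha:(di$zbeta - 1L), drop = FALSE]
  sb <- exp(draws[, di$lsb:(di$lsd - 1L), drop = FALSE])
  sd_ <- exp(draws[, di$lsd:(di$zc - 1L), drop = FALSE])
  g <- exp(draws[, di$ug:(di$zdelta - 1L), drop = FALSE])
  # per-draw Cholesky columns as n-vectors
  Lv <- vector("list", C)
  for (i in seq_len(C)) Lv[[i]] <- vector("list", C)
  Lv[[1]][[1]] <- rep(1, n)
  if (C > 1) {
    z <- tanh(draws[, di$zc:(di$lnu - 1L), drop = FALSE])
    t0 <- 0L
    for (i in 2:C) {
      rem <- rep(1, n)
      for (j in seq_len(i - 1L)) {
        zj <- z[, t0 + j]
        Lv[[i]][[j]] <- zj * sqrt(rem)
        rem <- rem * (1 - zj^2)
      }
      Lv[[i]][[i]] <- sqrt(pmax(rem, 0))
      t0 <- t0 + (i - 1L)
    }
  }
  cols <- list()
  for (ci in seq_len(C)) cols[[paste0("alpha[", cl[ci], "]")]] <- alpha[, ci]
  for (ci in seq_len(C)) cols[[paste0("R[", cl[ci], "]")]] <- stats::plogis(-alpha[, ci])
  for (ci in seq_len(C)) {
    for (p in seq_len(P)) {
      acc <- rep(0, n)
      for (j in seq_len(ci)) acc <- acc + Lv[[ci]][[j]] * draws[, di$zbeta - 1L + p + P * (j - 1L)]
      cols[[paste0("beta[", p, ",", cl[ci], "]")]] <- sb[, ci] * acc / sqrt(g[, p])
    }
  }
  for (ci in seq_len(C)) {
    for (e in seq_len(E)) {
      cols[[paste0("delta[", cl[ci], ",", e, "]")]] <-
        sd_[, ci] * draws[, di$zdelta - 1L + ci + C * (e - 1L)]
    }
  }
  for (ci in seq_len(C)) cols[[paste0("sigma_beta[", cl[ci], "]")]] <- sb[, ci]
  for (ci in seq_len(C)) cols[[paste0("sigma_delta[", cl[ci], "]")]] <- sd_[, ci]
  if (C > 1) {
    for (i in 2:C) {
      for (j in seq_len(i - 1L)) {
        acc <- rep(0, n)
        for (k in seq_len(j)) acc <- acc + Lv[[i]][[k]] * Lv[[j]][[k]]
        cols[[paste0("corr_beta[", i, ",", j, "]")]] <- acc
      }
    }
  }
  if (di$estimate_nu) cols[["nu"]] <- 2 + exp(draws[, di$lnu])
  do.call(cbind, cols)
}

#' Sample the posterior of the hierarchical phase model
#'
#' Runs the built-in No-U-Turn Hamiltonian Monte Carlo sampler on the
#' joint posterior. The first half of each chain is warmup (step-size
#' dual averaging and diagonal mass adaptation) and is discarded;
#' energies and divergence flags are recorded per post-warmup iteration.
#'
#' @param data A [phase_dataset()].
#' @param cfg A [prior_config()].
#' @param chains Number of chains (>= 2, required by the convergence
#'   diagnostics).
#' @param iterations Total iterations per chain; the first half is warmup.
#' @param seed Integer seed; fixing it makes the draws reproducible.
#' @param target_accept NUTS target acceptance statistic.
#' @param max_treedepth Maximum doubling depth per iteration.
#' @param prior_only If `TRUE` the likelihood is dropped and the sampler
#'   explores the prior (a validation mode).
#' @param gamma_scale Internal likelihood-corruption factor (the wrapped
#'   Cauchy scale is multiplied by this in the likelihood only); used by
#'   the simulation-based-calibration negative control. Leave at 1.
#' @return A `wc_fit` object: unconstrained and transformed draws,
#'   energies, divergence flags, and sampler metadata.
#' @export
sample_posterior <- function(data, cfg = prior_config(), chains = 4,
                             iterations = 4000, seed = 1,
                             target_accept = 0.9, max_treedepth = 10,
                             prior_only = FALSE, gamma_scale = 1) {
  stopifnot(inherits(data, "phase_dataset"))
  if (chains < 2) stop("at least 2 chains are required for diagnostics", call. = FALSE)
  if (iterations < 20) stop("`iterations` is too small", call. = FALSE)
  md <- model_data_list(data, cfg, gamma_scale = gamma_scale, prior_only = prior_only)
  lay <- data$layout
  di <- dim_info(md$P, md$C, md$E, cfg$estimate_nu)
  n_warmup <- floor(iterations / 2)
  n_keep <- iterations - n_warmup
  set.seed(seed)
  raw <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- random_init(di)
    raw[[ch]] <- cpp_nuts(md, init, n_warmup, n_keep,
                          target_accept = target_accept,
                          max_treedepth = max_treedepth)
  }
  draws <- array(NA_real_, dim = c(n_keep, di$D, chains))
  energy <- matrix(NA_real_, n_keep, chains)
  divergent <- matrix(FALSE, n_keep, chains)
  for (ch in seq_len(chains)) {
    draws[, , ch] <- raw[[ch]]$draws
    energy[, ch] <- raw[[ch]]$energy
    divergent[, ch] <- raw[[ch]]$divergent
  }
  tr1 <- transform_draws(draws[, , 1, drop = TRUE], di, cfg, lay)
  params <- array(NA_real_, dim = c(n_keep, ncol(tr1), chains),
                  dimnames = list(NULL, colnames(tr1), NULL))
  params[, , 1] <- tr1
  if (chains > 1) {
    for (ch in 2:chains) params[, , ch] <- transform_draws(draws[, , ch], di, cfg, lay)
  }
  structure(list(
    draws = draws, params = params, energy = energy, divergent = divergent,
    warmup_discarded = TRUE, n_warmup = n_warmup,
    stepsize = vapply(raw, function(r) r$stepsize, numeric(1)),
    treedepth = vapply(raw, function(r) mean(r$treedepth), numeric(1)),
    accept_stat = vapply(raw, function(r) mean(r$accept_stat), numeric(1)),
    layout = lay, cfg = cfg, frequency = data$frequency, seed = seed,
    dim_info = di
  ), class = "wc_fit")
}

#' @export
print.wc_fit <- function(x, ...) {
  cat(sprintf("<wc_fit> %d chains x %d draws (%d warmup discarded), %d parameters\n",
              dim(x$draws)[3], dim(x$draws)[1], x$n_warmup, x$dim_info$D))
  cat(sprintf("  divergences: %d, mean accept: %.2f\n",
              sum(x$divergent), mean(x$accept_stat)))
  invisible(x)
}

# pooled draws of one named transformed parameter
pooled_param <- function(fit, name) {
  if (!name %in% dimnames(fit$params)[[2]]) {
    stop(sprintf("unknown parameter `%s`", name), call. = FALSE)
  }
  as.vector(fit$params[, name, ])
}

#' Maximum a posteriori estimate
#'
#' Penalised-likelihood mode of the joint posterior in the unconstrained
#' space, found by L-BFGS-B with multiple jittered starts (the best of
#' `n_starts` local optima is returned).
#'
#' @param data A [phase_dataset()].
#' @param cfg A [prior_config()].
#' @param n_starts Number of jittered starting points.
#' @param seed Integer seed for the starts.
#' @param maxit Iteration cap per start.
#' @return A list: `params` (a [model_params()]), `R` (named per-condition
#'   mean resultant lengths `1 - logistic(alpha_c)`), `logpost`, and
#'   `convergence` (0 = converged).
#' @export
map_estimate <- function(data, cfg = prior_config(), n_starts = 5, seed = 1,
                         maxit = 500) {
  stopifnot(inherits(data, "phase_dataset"))
  md <- model_data_list(data, cfg)
  di <- dim_info(md$P, md$C, md$E, cfg$estimate_nu)
  set.seed(seed)
  fn <- function(q) {
    v <- cpp_logpost(q, md, gradient = FALSE)$lp
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(q) {
    r <- cpp_logpost(q, md, gradient = TRUE)
    if (!is.finite(r$lp)) rep(0, length(q)) else -r$grad
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- random_init(di)
    opt <- tryCatch(
      stats::optim(init, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("MAP optimisation failed from every start", call. = FALSE)
  params <- unpack_params(best$par, di, cfg)
  R <- stats::plogis(-params$alpha)
  names(R) <- data$layout$condition_labels
  list(params = params, R = R, logpost = -best$value,
       convergence = best$convergence)
}

#' Point-estimate trace of the mean resultant across a frequency grid
#'
#' Maps [map_estimate()] over a list of per-frequency datasets, returning
#' the per-condition mean resultant length at each frequency (the
#' fast, optimisation-based companion to the full posterior fits).
#'
#' @param datasets A list of [phase_dataset()]s, one per frequency.
#' @param cfg A [prior_config()].
#' @param ... Passed to [map_estimate()].
#' @return A data.frame with columns `frequency`, `condition`, `R`.
#' @export
map_trace <- function(datasets, cfg = prior_config(), ...) {
  out <- lapply(datasets, function(d) {
    est <- map_estimate(d, cfg, ...)
    data.frame(frequency = d$frequency,
               condition = names(est$R), R = as.numeric(est$R),
               row.names = NULL)
  })
  do.call(rbind, out)
}
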