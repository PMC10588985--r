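#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the classical potential-scale-reduction
#' statistic is computed over the resulting half-chains, comparing
#' between- and within-chain means and variances. Values near 1 indicate
#' convergence; < 1.05 is conventionally acceptable, < 1.02 desirable.
#'
#' @param draws A matrix (iterations x chains) of draws of one scalar
#'   parameter, with at least 2 chains and 4 draws per chain.
#' @return The split R-hat statistic.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2 || nrow(draws) < 4) {
    stop("split_rhat needs >= 2 chains with >= 4 draws each", call. = FALSE)
  }
  sp <- split_chains(draws)
  if (any(apply(sp, 2, stats::var) == 0) || stats::var(as.vector(sp)) == 0) {
    stop("draws have zero variance; R-hat is undefined", call. = FALSE)
  }
  n <- nrow(sp); m <- ncol(sp)
  means <- colMeans(sp)
  W <- mean(apply(sp, 2, stats::var))
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_chains <- function(draws) {
  n <- nrow(draws)
  h <- floor(n / 2)
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1):n, , drop = FALSE])
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size over split chains, using
#' FFT autocovariance estimates combined across chains and Geyer's initial
#' monotone positive sequence truncation.
#'
#' @inheritParams split_rhat
#' @return The estimated effective number of independent draws.
#' @export
effective_sample_size <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4) stop("too few draws for an ESS estimate", call. = FALSE)
  sp <- if (ncol(draws) >= 2) split_chains(draws) else draws
  n <- nrow(sp); m <- ncol(sp)
  if (stats::var(as.vector(sp)) == 0) {
    stop("draws have zero variance; ESS is undefined", call. = FALSE)
  }
  acov <- apply(sp, 2, autocovariance_fft)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  mean_acov <- rowMeans(acov)
  var_plus <- mean(acov[1, ]) * (n - 1) / n +
    (if (m > 1) stats::var(colMeans(sp)) else 0)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial monotone positive sequence on paired lag sums,
  # starting from lag 1 (rho[1] is lag 0)
  max_t <- length(rho) - 1
  s <- 0
  lag <- 1
  prev <- Inf
  while (lag + 1 <= max_t) {
    pair <- rho[lag + 1] + rho[lag + 2]
    if (is.na(pair) || pair < 0) break
    pair <- min(pair, prev)   # enforce monotone decrease
    s <- s + pair
    prev <- pair
    lag <- lag + 2
  }
  tau <- 1 + 2 * s
  max(n * m / tau, 1e-12)
}

autocovariance_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, nfft - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n
}

#' Energy Bayesian fraction of missing information
#'
#' `sum(diff(E)^2) / sum((E - mean(E))^2)` per chain, comparing the
#' transitional energy distribution with the marginal one. Independent
#' energies give values near 2; heavy-tailed posteriors that the momentum
#' resampling cannot traverse give small values (< 0.3 is the usual
#' warning level).
#'
#' @param energies Numeric vector (one chain) or matrix
#'   (iterations x chains) of Hamiltonian energies.
#' @return Numeric vector of per-chain E-BFMI values.
#' @export
energy_bfmi <- function(energies) {
  energies <- as.matrix(energies)
  if (nrow(energies) < 3) stop("too few energies", call. = FALSE)
  apply(energies, 2, function(e) {
    v <- sum((e - mean(e))^2)
    if (v == 0) stop("energies are constant", call. = FALSE)
    sum(diff(e)^2) / v
  })
}

#' Highest density interval
#'
#' The narrowest contiguous interval containing at least the requested
#' probability mass: over sorted draws, the shortest window of
#' `floor(mass * n) + 1` points (leftmost on ties).
#'
#' @param samples Numeric draws of a scalar quantity (>= 10).
#' @param mass Probability mass in (0, 1); default 0.90.
#' @return Named numeric vector `c(lower, upper, mass)`.
#' @export
hdi <- function(samples, mass = 0.90) {
  if (length(samples) < 10) stop("need at least 10 draws for an HDI", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) {
    stop("`mass` must be in (0, 1)", call. = FALSE)
  }
  x <- sort(samples)
  n <- length(x)
  m <- min(n, floor(mass * n) + 1L)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)   # leftmost narrowest window
  c(lower = x[i], upper = x[i + m - 1L], mass = mass)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for every transformed model
#' parameter, E-BFMI per chain, and the divergence count.
#'
#' @param fit A `wc_fit` from [sample_posterior()].
#' @return A list with `parameters` (data.frame: parameter, rhat, ess,
#'   ess_ratio), `ebfmi`, `divergence_count`, and `max_rhat`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "wc_fit"))
  pn <- dimnames(fit$params)[[2]]
  total <- dim(fit$params)[1] * dim(fit$params)[3]
  stats_ <- lapply(pn, function(nm) {
    d <- fit$params[, nm, ]
    rh <- tryCatch(split_rhat(d), error = function(e) NA_real_)
    es <- tryCatch(effective_sample_size(d), error = function(e) NA_real_)
    c(rhat = rh, ess = es)
  })
  df <- data.frame(parameter = pn,
                   rhat = vapply(stats_, `[[`, numeric(1), "rhat"),
                   ess = vapply(stats_, `[[`, numeric(1), "ess"),
                   row.names = NULL)
  df$ess_ratio <- df$ess / total
  list(parameters = df,
       ebfmi = energy_bfmi(fit$energy),
       divergence_count = sum(fit$divergent),
       max_rhat = max(df$rhat, na.rm = TRUE))
}

#' Posterior summary table
#'
#' Chain-pooled mean, median, sd, HDI bounds, split R-hat and ESS for each
#' transformed parameter, in tidy long format (one row per parameter).
#'
#' @param object A `wc_fit`.
#' @param mass HDI mass.
#' @param ... Unused.
#' @return A data.frame.
#' @export
summary.wc_fit <- function(object, mass = 0.90, ...) {
  pn <- dimnames(object$params)[[2]]
  dg <- diagnostics(object)
  rows <- lapply(pn, function(nm) {
    x <- as.vector(object$params[, nm, ])
    h <- hdi(x, mass)
    data.frame(parameter = nm, mean = mean(x), median = stats::median(x),
               sd = stats::sd(x), hdi_low = h[["lower"]], hdi_high = h[["upper"]])
  })
  out <- do.call(rbind, rows)
  out$rhat <- dg$parameters$rhat
  out$ess <- dg$parameters$ess
  out
}

#' Write a posterior summary as tidy CSV
#'
#' @param fit A `wc_fit`.
#' @param path Output file.
#' @param mass HDI mass.
#' @return The path, invisibly.
#' @export
write_summary <- function(fit, path, mass = 0.90) {
  utils::write.csv(summary(fit, mass = mass), path, row.names = FALSE)
  invisible(path)
}
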