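test_that("itpc table computes per-cell coherence and electrode means", {
  data <- simulate_flat(c(0.6, 0.2), P = 3, E = 4, K = 2000, seed = 1)
  tab <- itpc_table(data)
  expect_equal(dim(tab$values), c(3, 2, 4))
  expect_true(all(tab$values >= 0 & tab$values <= 1))
  expect_lt(max(abs(tab$values[, 1, ] - 0.6)), 0.05)
  expect_lt(max(abs(tab$values[, 2, ] - 0.2)), 0.05)
  expect_equal(tab$electrode_mean[2, 1], mean(tab$values[2, 1, ]))
  # permuting trials leaves the table unchanged
  shuf <- data
  shuf$phases <- data$phases[, , , sample(dim(data$phases)[4]), drop = FALSE]
  expect_equal(itpc_table(shuf)$values, tab$values, tolerance = 1e-12)
})

test_that("empty cells are excluded with a warning", {
  data <- simulate_flat(0.5, P = 2, E = 2, K = 4, seed = 2)
  data$phases[1, 1, 2, ] <- NA
  expect_warning(tab <- itpc_table(data), "empty cell")
  expect_true(is.na(tab$values[1, 1, 2]))
  expect_false(anyNA(tab$values[2, , ]))
})

test_that("per-electrode condition differences average over participants", {
  data <- simulate_flat(c(0.5, 0.5), P = 12, E = 6, K = 400, seed = 3)
  tab <- itpc_table(data)
  expect_equal(unname(electrode_condition_difference(tab, 1, 1)), rep(0, 6))
  d <- electrode_condition_difference(tab, 1, 2)
  expect_equal(unname(d[3]),
               mean(tab$values[, 1, 3] - tab$values[, 2, 3]))
  dc <- electrode_condition_difference(tab, 1, 2, centre = TRUE)
  expect_equal(sum(dc), 0, tolerance = 1e-12)
  # planted boost at one electrode dominates the difference
  lay <- experiment_layout(12, 2, 6, 60)
  params <- flat_params(c(0.4, 0.4), P = 12, E = 6, seed = 4)
  params$delta[1, 5] <- -1.5          # condition 1, electrode 5: higher R
  boosted <- simulate_dataset(params, lay, seed = 5)
  db <- electrode_condition_difference(itpc_table(boosted), 1, 2)
  expect_equal(unname(which.max(db)), 5)
})

test_that("wilcoxon p-values match brute-force sign enumeration", {
  # oracle: exact two-sided p by enumerating all 2^n sign assignments of |d|
  brute_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p_ge <- mean(v_all >= v_obs); p_le <- mean(v_all <= v_obs)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(5)
  for (n in c(5, 7, 10)) {
    for (rep_i in 1:4) {
      d <- round(stats::rnorm(n, 0.3), 3)
      d <- d[d != 0]
      if (length(d) < 5) next
      w <- wilcoxon_signed_rank(d)
      expect_equal(w$p_value, brute_p(d), tolerance = 1e-12)
    }
  }
  # all-positive differences at n = 5: the classical 2/2^5 two-sided p
  w5 <- wilcoxon_signed_rank(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(w5$p_value, 0.0625, tolerance = 1e-12)
  # mirror symmetry
  d <- c(0.4, -0.1, 0.25, 0.7, -0.3, 0.2)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcoxon_signed_rank(-d)$p_value)
  # zero differences dropped and counted
  wz <- wilcoxon_signed_rank(c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0))
  expect_equal(wz$n_zero, 2)
  expect_equal(wz$n_used, 5)
  expect_error(wilcoxon_signed_rank(c(0.1, -0.2, 0.3, 0.4)), "at least 5")
})

test_that("wilcoxon holds its nominal type-I error under the null", {
  set.seed(6)
  n_rep <- 10000; n <- 16
  # V statistic and exact p through the signrank distribution (no ties
  # with continuous data)
  rej <- vapply(seq_len(n_rep), function(i) {
    d <- stats::rnorm(n)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
    min(p, 1) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.01)
  # spot-check agreement of the package wrapper with the direct computation
  d <- stats::rnorm(n)
  r <- rank(abs(d)); v <- sum(r[d > 0])
  p_direct <- min(1, 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n)))
  expect_equal(wilcoxon_signed_rank(d)$p_value, p_direct, tolerance = 1e-12)
})

test_that("wilcoxon confidence interval covers the true shift", {
  set.seed(7)
  w <- wilcoxon_signed_rank(stats::rnorm(40, 0.5, 0.2))
  expect_true(w$conf_int[1] < 0.5 && w$conf_int[2] > 0.5)
  expect_equal(w$estimate, 0.5, tolerance = 0.1)
})

test_that("knn adjacency is symmetric and montage files round-trip", {
  set.seed(8)
  coords <- cbind(stats::runif(10), stats::runif(10))
  rownames(coords) <- paste0("E", 1:10)
  adj <- knn_adjacency(coords, k = 3)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(all(rowSums(adj) >= 3))
  path <- tempfile()
  writeLines(sprintf("%s %.4f %.4f", rownames(coords), coords[, 1], coords[, 2]), path)
  back <- read_montage(path)
  expect_equal(unname(back), unname(coords), tolerance = 1e-4)
  expect_equal(rownames(back), rownames(coords))
})
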