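#' ITPC table of a phase dataset
#'
#' Inter-trial phase coherence per (participant, condition, electrode)
#' cell, plus the electrode-averaged trace per participant and condition
#' (the quantity classical group analyses are run on). Cells with no
#' observed trials are excluded as `NA` with a warning.
#'
#' @param data A [phase_dataset()].
#' @return An object of class `itpc_table`: `values` (P x C x E),
#'   `electrode_mean` (P x C), and the layout.
#' @export
itpc_table <- function(data) {
  stopifnot(inherits(data, "phase_dataset"))
  ph <- data$phases
  n_obs <- apply(!is.na(ph), c(1, 2, 3), sum)
  re <- apply(cos(ph), c(1, 2, 3), sum, na.rm = TRUE)
  im <- apply(sin(ph), c(1, 2, 3), sum, na.rm = TRUE)
  vals <- sqrt(re^2 + im^2) / n_obs
  vals[n_obs == 0] <- NA_real_
  if (any(n_obs == 0)) {
    warning(sprintf("%d empty cell(s) excluded from the ITPC table", sum(n_obs == 0)),
            call. = FALSE)
  }
  vals <- pmin(vals, 1)
  dim(vals) <- dim(ph)[1:3]
  dimnames(vals) <- dimnames(ph)[1:3]
  structure(list(values = vals,
                 electrode_mean = apply(vals, c(1, 2), mean, na.rm = TRUE),
                 layout = data$layout, frequency = data$frequency),
            class = "itpc_table")
}

#' @export
print.itpc_table <- function(x, ...) {
  cat(sprintf("<itpc_table> %s, mean coherence %.3f\n",
              paste(dim(x$values), collapse = " x "),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

resolve_condition_itpc <- function(table, c) {
  cl <- table$layout$condition_labels
  if (is.character(c)) {
    i <- match(c, cl)
    if (is.na(i)) stop(sprintf("unknown condition `%s`", c), call. = FALSE)
    return(i)
  }
  as.integer(c)
}

#' Participant-averaged per-electrode ITPC condition difference
#'
#' \eqn{\Delta\bar R_e = \langle R(p, c_1, e) - R(p, c_2, e)\rangle_p} per
#' electrode. Because the ITPC is upward-biased, topographic displays
#' usually subtract the across-electrode mean; `centre = TRUE` does so
#' (the centred values sum to zero exactly).
#'
#' @param table An [itpc_table()].
#' @param c1,c2 Condition labels or indices.
#' @param centre Subtract the across-electrode mean?
#' @return Named numeric vector, one value per electrode.
#' @export
electrode_condition_difference <- function(table, c1, c2, centre = FALSE) {
  stopifnot(inherits(table, "itpc_table"))
  i1 <- resolve_condition_itpc(table, c1)
  i2 <- resolve_condition_itpc(table, c2)
  d <- colMeans(table$values[, i1, , drop = TRUE] -
                table$values[, i2, , drop = TRUE], na.rm = TRUE)
  if (centre) d <- d - mean(d)
  names(d) <- table$layout$electrode_labels
  d
}

#' Paired Wilcoxon signed-rank test with a location CI
#'
#' A thin wrapper over [stats::wilcox.test()] for paired differences:
#' exact enumeration p-values for up to 25 non-zero differences, a normal
#' approximation with continuity correction above, and the
#' Hodges-Lehmann interval for the location shift. Zero differences are
#' dropped (the signed-rank convention) and their count reported.
#'
#' @param x Numeric vector of paired differences (or first member of the
#'   pair when `y` is given).
#' @param y Optional second member; the test is run on `x - y`.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param conf_level Confidence level for the Hodges-Lehmann interval.
#' @return A list: `p_value`, `statistic`, `conf_int`, `estimate`,
#'   `n_used`, `n_zero`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 conf_level = 0.95) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) < 5) {
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative,
                       exact = length(d) <= 25, correct = TRUE,
                       conf.int = TRUE, conf.level = conf_level))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       conf_int = unname(wt$conf.int), estimate = unname(wt$estimate),
       n_used = length(d), n_zero = n_zero)
}

#' k-nearest-neighbour electrode adjacency
#'
#' Builds a symmetric adjacency matrix from 2-d montage coordinates: each
#' electrode is connected to its `k` nearest neighbours (union over both
#' directions).
#'
#' @param coords Two-column matrix of electrode positions, one row per
#'   electrode (rownames used as labels if present).
#' @param k Number of neighbours (default 4).
#' @return Logical adjacency matrix with `FALSE` diagonal.
#' @export
knn_adjacency <- function(coords, k = 4) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2 || ncol(coords) != 2) stop("`coords` must be an n x 2 matrix, n >= 2",
                                       call. = FALSE)
  k <- min(k, n - 1)
  dd <- as.matrix(stats::dist(coords))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dd[i, ])[2:(k + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  if (!is.null(rownames(coords))) dimnames(adj) <- list(rownames(coords), rownames(coords))
  adj
}

#' Read a montage file
#'
#' Whitespace-separated file with one electrode per line:
#' `label x y`.
#'
#' @param path File path.
#' @return Two-column coordinate matrix with electrode labels as rownames.
#' @export
read_montage <- function(path) {
  tb <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y"),
                          colClasses = c("character", "numeric", "numeric"))
  m <- as.matrix(tb[, c("x", "y")])
  rownames(m) <- tb$label
  m
}

# per-electrode paired statistic over participants; sign flips supplied as
# a +-1 vector (identity for the observed statistic).  diffs is P x E.
# For the paired t, sum(x) changes under flips but sum(x^2) does not,
# which makes the permutation null cheap.
electrode_stat <- function(diffs, signs, type = c("t", "wilcoxon")) {
  type <- match.arg(type)
  P <- nrow(diffs)
  x <- diffs * signs
  if (type == "t") {
    sx <- colSums(x)
    ssq <- colSums(diffs^2)          # invariant under sign flips
    mean_ <- sx / P
    var_ <- (ssq - sx^2 / P) / (P - 1)
    var_[var_ <= 0] <- NA_real_
    mean_ / sqrt(var_ / P)
  } else {
    apply(x, 2, function(v) {
      v <- v[v != 0]
      if (length(v) < 2) return(0)
      r <- rank(abs(v))
      w <- sum(r[v > 0])
      n <- length(v)
      (w - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    })
  }
}

#' Cluster-based permutation test over electrodes
#'
#' The max-statistic cluster permutation scheme for paired condition
#' comparisons of ITPC: a paired statistic per electrode (t by default,
#' or a Wilcoxon signed-rank z), thresholded at the two-sided
#' cluster-forming level; supra-threshold electrodes of common sign are
#' grouped into connected clusters under the supplied adjacency graph;
#' cluster mass is the summed statistic; and the null distribution of the
#' maximal absolute cluster mass is built by randomly swapping the
#' condition labels within participant. The cluster p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`. Electrodes inside a
#' significant cluster are not individually significant.
#'
#' @param table An [itpc_table()].
#' @param c1,c2 Condition labels or indices.
#' @param adjacency Logical/0-1 adjacency matrix over all electrodes
#'   (must describe a connected graph).
#' @param threshold Two-sided cluster-forming p-value (default 0.05).
#' @param n_perm Number of permutations (>= 500).
#' @param seed Integer seed.
#' @param stat Cluster statistic: `"t"` (paired t) or `"wilcoxon"`
#'   (signed-rank z).
#' @return An object of class `cluster_result`: per-cluster electrode
#'   sets, masses and p-values, the per-electrode statistics, and the
#'   permutation settings.
#' @export
cluster_permutation_test <- function(table, c1, c2, adjacency,
                                     threshold = 0.05, n_perm = 1000,
                                     seed = 1, stat = c("t", "wilcoxon")) {
  stopifnot(inherits(table, "itpc_table"))
  stat <- match.arg(stat)
  if (n_perm < 500) stop("`n_perm` must be at least 500", call. = FALSE)
  i1 <- resolve_condition_itpc(table, c1)
  i2 <- resolve_condition_itpc(table, c2)
  E <- table$layout$n_electrodes
  adjacency <- adjacency != 0
  if (!all(dim(adjacency) == c(E, E))) {
    stop("`adjacency` must cover all electrodes", call. = FALSE)
  }
  gr_full <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  if (!igraph::is_connected(gr_full)) {
    stop("the electrode adjacency graph is disconnected", call. = FALSE)
  }
  diffs <- table$values[, i1, , drop = TRUE] - table$values[, i2, , drop = TRUE]
  diffs <- as.matrix(diffs)
  P <- nrow(diffs)
  crit <- if (stat == "t") stats::qt(1 - threshold / 2, df = P - 1) else
    stats::qnorm(1 - threshold / 2)

  find_clusters <- function(s) {
    supra <- which(!is.na(s) & abs(s) > crit)
    if (length(supra) == 0) return(list())
    out <- list()
    for (sgn in c(1, -1)) {
      nodes <- supra[sign(s[supra]) == sgn]
      if (length(nodes) == 0) next
      sub <- igraph::induced_subgraph(gr_full, nodes)
      comp <- igraph::components(sub)
      for (ci in seq_len(comp$no)) {
        members <- nodes[comp$membership == ci]
        out[[length(out) + 1L]] <- list(electrodes = members,
                                        mass = sum(s[members]))
      }
    }
    out
  }

  set.seed(seed)
  s_obs <- electrode_stat(diffs, rep(1, P), stat)
  clusters <- find_clusters(s_obs)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), P, replace = TRUE)
    cl <- find_clusters(electrode_stat(diffs, signs, stat))
    null_max[b] <- if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }
  p <- vapply(clusters, function(cl) {
    (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
  }, numeric(1))
  structure(list(
    clusters = lapply(clusters, `[[`, "electrodes"),
    cluster_mass = vapply(clusters, `[[`, numeric(1), "mass"),
    p_value = p, n_permutations = n_perm, statistic = s_obs,
    stat_type = stat, threshold = threshold, seed = seed,
    electrode_labels = table$layout$electrode_labels
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations (%s statistic)\n",
              length(x$clusters), x$n_permutations, x$stat_type))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %s | mass %.2f | p = %.4f\n", i,
                paste(x$electrode_labels[x$clusters[[i]]], collapse = ", "),
                x$cluster_mass[i], x$p_value[i]))
  }
  invisible(x)
}

#' Tidy data.frame of a cluster result
#' @param result A `cluster_result`.
#' @return A data.frame, one row per cluster.
#' @export
cluster_result_table <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (length(result$clusters) == 0) {
    return(data.frame(cluster = integer(0), electrodes = character(0),
                      mass = numeric(0), p_value = numeric(0)))
  }
  data.frame(
    cluster = seq_along(result$clusters),
    electrodes = vapply(result$clusters, function(e)
      paste(result$electrode_labels[e], collapse = ";"), character(1)),
    mass = result$cluster_mass,
    p_value = result$p_value)
}
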