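# Phase-table CSV input/output, DFT phase extraction, and configuration files.

#' Read a long-format phase table
#'
#' CSV with header columns `participant, condition, electrode, trial,
#' phase, frequency` (one row per observed trial). The key
#' (participant, condition, electrode, trial, frequency) must be unique;
#' duplicates are a fatal error naming the offending key. Phases outside
#' \eqn{[-\pi, \pi)} are wrapped on load with a warning. Cells absent
#' from the file are missing (masked), not zero.
#'
#' @param path CSV file path.
#' @param frequency Optional: keep only rows at this frequency (required
#'   when the file contains several).
#' @return A [phase_dataset()].
#' @export
read_phase_table <- function(path, frequency = NULL) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "electrode", "trial", "phase", "frequency")
  if (!all(need %in% names(tb))) {
    stop(sprintf("phase table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(tb$phase) | !is.finite(suppressWarnings(as.numeric(tb$trial))))
  if (length(bad) > 0) {
    stop(sprintf("malformed phase/trial values at data row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  freqs <- unique(tb$frequency)
  if (is.null(frequency)) {
    if (length(freqs) > 1) {
      stop("file contains several frequencies; pass `frequency`", call. = FALSE)
    }
    frequency <- freqs[1]
  }
  tb <- tb[tb$frequency == frequency, , drop = FALSE]
  if (nrow(tb) == 0) stop("no rows at the requested frequency", call. = FALSE)
  key <- paste(tb$participant, tb$condition, tb$electrode, tb$trial, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate key(s) in phase table, e.g. (participant, condition, electrode, trial) = (%s)",
                 gsub("\\|", ", ", key[which(duplicated(key))[1]])), call. = FALSE)
  }
  p_lab <- unique(tb$participant); c_lab <- unique(tb$condition)
  e_lab <- unique(tb$electrode)
  K <- max(tb$trial)
  lay <- experiment_layout(length(p_lab), length(c_lab), length(e_lab), K,
                           condition_labels = c_lab, electrode_labels = e_lab,
                           participant_labels = as.character(p_lab))
  ph <- array(NA_real_, dim = c(length(p_lab), length(c_lab), length(e_lab), K))
  pi_ <- match(tb$participant, p_lab); ci <- match(tb$condition, c_lab)
  ei <- match(tb$electrode, e_lab)
  ph[cbind(pi_, ci, ei, tb$trial)] <- tb$phase
  phase_dataset(ph, frequency = frequency, layout = lay)
}

#' Write a phase dataset as a long-format CSV
#'
#' Inverse of [read_phase_table()]; only observed trials are written.
#'
#' @param data A [phase_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phase_table <- function(data, path) {
  stopifnot(inherits(data, "phase_dataset"))
  lay <- data$layout
  idx <- which(!is.na(data$phases), arr.ind = TRUE)
  tb <- data.frame(
    participant = lay$participant_labels[idx[, 1]],
    condition = lay$condition_labels[idx[, 2]],
    electrode = lay$electrode_labels[idx[, 3]],
    trial = idx[, 4],
    phase = data$phases[idx],
    frequency = data$frequency)
  tb <- tb[order(tb$participant, tb$condition, tb$electrode, tb$trial), ]
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' Extract the phase at a target frequency from an epoch
#'
#' The argument of the discrete Fourier coefficient at the bin nearest
#' `target_f` (cosine convention: a pure cosine at an exact bin has phase
#' 0, a pure sine has phase \eqn{-\pi/2}). No zero-padding or
#' interpolation: the realised bin frequency is returned alongside and
#' should equal the stimulation frequency when the epoch length is
#' matched to it.
#'
#' @param epoch Numeric vector, the time-series of one epoch.
#' @param sample_rate Sampling rate in Hz.
#' @param target_f Target frequency in Hz (strictly below Nyquist).
#' @return A list: `phase` (radians in \eqn{[-\pi,\pi)}), `frequency`
#'   (the realised bin frequency, Hz), `bin` (0-based bin index).
#' @export
extract_phase <- function(epoch, sample_rate, target_f) {
  n <- length(epoch)
  if (n < 2) stop("epoch must have at least 2 samples", call. = FALSE)
  if (!is.finite(target_f) || target_f <= 0 || target_f >= sample_rate / 2) {
    stop("`target_f` must lie in (0, Nyquist)", call. = FALSE)
  }
  df <- sample_rate / n
  bin <- round(target_f / df)
  bin <- max(1, min(bin, floor(n / 2)))
  coef <- stats::fft(epoch)[bin + 1]
  list(phase = wrap_angle(Arg(coef)), frequency = bin * df, bin = bin)
}

#' Write the default prior/sampler configuration to a YAML file
#'
#' @param path Output path.
#' @param cfg A [prior_config()] (defaults used when omitted).
#' @return The path, invisibly.
#' @export
write_prior_config <- function(path, cfg = prior_config()) {
  stopifnot(inherits(cfg, "prior_config"))
  flat <- cfg[setdiff(names(cfg), "estimate_nu")]
  flat$nu <- if (cfg$estimate_nu) "estimate" else cfg$nu
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a prior configuration from a YAML file
#'
#' @param path YAML file written by [write_prior_config()] (unknown keys
#'   are rejected).
#' @return A [prior_config()].
#' @export
read_prior_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(prior_config)), "")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(prior_config, vals)
}
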