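#' Experiment layout
#'
#' Dimensions and labels of a frequency-tagged phase dataset: `P`
#' participants by `C` conditions by `E` electrodes, with up to `K` trials
#' per cell.
#'
#' @param n_participants,n_conditions,n_electrodes,n_trials Positive counts.
#' @param condition_labels,electrode_labels,participant_labels Optional
#'   unique character labels; defaults are generated.
#' @return An object of class `experiment_layout`.
#' @examples
#' experiment_layout(4, 2, 8, 10)
#' @export
experiment_layout <- function(n_participants, n_conditions, n_electrodes, n_trials,
                              condition_labels = NULL, electrode_labels = NULL,
                              participant_labels = NULL) {
  counts <- c(n_participants, n_conditions, n_electrodes, n_trials)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("all layout counts must be integers >= 1", call. = FALSE)
  }
  lbl <- function(given, n, prefix) {
    if (is.null(given)) return(paste0(prefix, seq_len(n)))
    given <- as.character(given)
    if (length(given) != n || anyDuplicated(given)) {
      stop(sprintf("labels for %s must be %d unique values", prefix, n), call. = FALSE)
    }
    given
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_conditions = as.integer(n_conditions),
    n_electrodes = as.integer(n_electrodes),
    n_trials = as.integer(n_trials),
    participant_labels = lbl(participant_labels, n_participants, "P"),
    condition_labels = lbl(condition_labels, n_conditions, "cond"),
    electrode_labels = lbl(electrode_labels, n_electrodes, "E")
  ), class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf("<experiment_layout> %d participants x %d conditions x %d electrodes x %d trials\n",
              x$n_participants, x$n_conditions, x$n_electrodes, x$n_trials))
  invisible(x)
}

#' Preset layouts for the two published study designs
#'
#' `"phrase"` mirrors a grammatical-phrase frequency-tagging design
#' (16 participants, 6 conditions, 32 electrodes, 24 trials; phrase rate
#' 1.5625 Hz). `"statistical_learning"` mirrors an artificial-language
#' statistical-learning design (39 participants, 2 conditions, 64
#' electrodes; pseudoword rate 1.33 Hz) with 66 trials per cell.
#'
#' @param name One of `"phrase"`, `"statistical_learning"`.
#' @return An `experiment_layout`.
#' @export
layout_preset <- function(name = c("phrase", "statistical_learning")) {
  name <- match.arg(name)
  switch(name,
    phrase = experiment_layout(
      16, 6, 32, 24,
      condition_labels = c("AN", "AV", "MP", "ML", "RV", "RR")
    ),
    statistical_learning = experiment_layout(
      39, 2, 64, 66,
      condition_labels = c("EXP", "BL")
    )
  )
}

#' Frequency for a preset layout
#' @param name Preset name as in [layout_preset()].
#' @return Analysis frequency in Hz.
#' @export
preset_frequency <- function(name = c("phrase", "statistical_learning")) {
  name <- match.arg(name)
  switch(name, phrase = 1.5625, statistical_learning = 1.33)
}

#' Phase dataset
#'
#' A container for one analysis frequency: a `P x C x E x K` array of
#' phase angles with `NA` marking missing trials (missingness is explicit;
#' no sentinel angles). Phases outside \eqn{[-\pi,\pi)} are wrapped on
#' entry with a warning.
#'
#' @param phases 4-d numeric array `(participant, condition, electrode, trial)`.
#' @param frequency Analysis frequency in Hz (metadata).
#' @param layout Optional [experiment_layout()]; constructed from the
#'   array dimensions when omitted.
#' @return An object of class `phase_dataset`.
#' @export
phase_dataset <- function(phases, frequency = NA_real_, layout = NULL) {
  if (!is.array(phases) || length(dim(phases)) != 4L) {
    stop("`phases` must be a 4-d array (P x C x E x K)", call. = FALSE)
  }
  d <- dim(phases)
  if (is.null(layout)) {
    layout <- experiment_layout(d[1], d[2], d[3], d[4])
  } else {
    stopifnot(inherits(layout, "experiment_layout"))
    if (!all(d == c(layout$n_participants, layout$n_conditions,
                    layout$n_electrodes, layout$n_trials))) {
      stop("array dimensions do not match the layout", call. = FALSE)
    }
  }
  obs <- !is.na(phases)
  if (any(!is.finite(phases[obs]))) {
    stop("phases must be finite or NA", call. = FALSE)
  }
  out_of_range <- obs & (phases < -pi | phases >= pi)
  if (any(out_of_range)) {
    warning(sprintf("%d phase(s) outside [-pi, pi) were wrapped", sum(out_of_range)),
            call. = FALSE)
    phases[out_of_range] <- wrap_angle(phases[out_of_range])
  }
  dimnames(phases) <- list(layout$participant_labels, layout$condition_labels,
                           layout$electrode_labels, NULL)
  structure(list(phases = phases, layout = layout, frequency = frequency),
            class = "phase_dataset")
}

#' @export
print.phase_dataset <- function(x, ...) {
  n_obs <- sum(!is.na(x$phases))
  cat(sprintf("<phase_dataset> %s at %.4g Hz, %d observed trials\n",
              paste(dim(x$phases), collapse = " x "), x$frequency, n_obs))
  invisible(x)
}

#' Subset a phase dataset
#'
#' Keeps the first `participants` participants and/or the first `trials`
#' trials per cell (used by the data-efficiency analyses, which drop
#' participants/trials from the end of the recording order).
#'
#' @param data A [phase_dataset()].
#' @param participants,trials Counts to retain (default: all).
#' @return A [phase_dataset()].
#' @export
subset_phases <- function(data, participants = NULL, trials = NULL) {
  stopifnot(inherits(data, "phase_dataset"))
  lay <- data$layout
  p_keep <- seq_len(if (is.null(participants)) lay$n_participants else participants)
  k_keep <- seq_len(if (is.null(trials)) lay$n_trials else trials)
  if (max(p_keep) > lay$n_participants || max(k_keep) > lay$n_trials) {
    stop("subset exceeds the available participants or trials", call. = FALSE)
  }
  ph <- data$phases[p_keep, , , k_keep, drop = FALSE]
  new_layout <- experiment_layout(
    length(p_keep), lay$n_conditions, lay$n_electrodes, length(k_keep),
    condition_labels = lay$condition_labels,
    electrode_labels = lay$electrode_labels,
    participant_labels = lay$participant_labels[p_keep]
  )
  phase_dataset(ph, frequency = data$frequency, layout = new_layout)
}
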