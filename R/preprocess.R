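# Baseline correction and artifact rejection.

#' Artifact rejection specification
#'
#' A 200-ms window moves across -100..500 ms in 50-ms steps; a trial is marked
#' for rejection when the peak-to-peak voltage within any window exceeds 50 uV
#' on VEOG (blinks) or 20 uV on HEOG (horizontal eye movements). Independently,
#' trials whose baseline-corrected EEG exceeds +/-75 uV anywhere in the epoch
#' (high-amplitude noise or muscle activity) are rejected.
#'
#' @param window_ms moving-window width (ms).
#' @param step_ms window step (ms).
#' @param scan_span_ms two-element span the windows must cover, in ms.
#' @param veog_uv,heog_uv peak-to-peak thresholds (uV).
#' @param abs_uv absolute EEG threshold (uV), applied over the full epoch.
#' @return a `rejection_spec`.
#' @export
rejection_spec <- function(window_ms = 200, step_ms = 50,
                           scan_span_ms = c(-100, 500),
                           veog_uv = 50, heog_uv = 20, abs_uv = 75) {
  if (any(c(window_ms, step_ms, veog_uv, heog_uv, abs_uv) <= 0)) {
    stop_ag("window, step and thresholds must be positive")
  }
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 scan_span_ms = scan_span_ms, veog_uv = veog_uv,
                 heog_uv = heog_uv, abs_uv = abs_uv),
            class = "rejection_spec")
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (default -200..0 ms before cue onset).
#'
#' @param epochs an [epoch_set()].
#' @param window baseline [time_window()] or numeric pair (ms).
#' @return the baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  si <- window_sample_idx(epochs, window)
  d <- dim(epochs$data)
  bl <- epochs$data[, , si, drop = FALSE]
  dim(bl) <- c(d[1] * d[2], length(si))
  epochs$data <- epochs$data - as.vector(rowMeans(bl))  # recycles over samples
  epochs
}

moving_window_starts <- function(spec) {
  seq(spec$scan_span_ms[1], spec$scan_span_ms[2] - spec$window_ms,
      by = spec$step_ms)
}

#' Detect artifact trials
#'
#' Applies the moving-window peak-to-peak EOG rules and the absolute-amplitude
#' EEG rule of a [rejection_spec()]. The absolute rule is evaluated on
#' baseline-corrected data so the decision is invariant to constant channel
#' offsets (peak-to-peak already is).
#'
#' @param epochs an [epoch_set()].
#' @param spec a [rejection_spec()].
#' @return a tibble with one row per trial: `trial_id`, `eog` (EOG rule hit),
#'   `abs` (absolute rule hit), `rejected`.
#' @export
detect_artifacts <- function(epochs, spec = rejection_spec()) {
  for (ch in c("VEOG", "HEOG")) {
    if (!ch %in% epochs$channel_names) {
      stop_ag(sprintf("EOG channel '%s' missing", ch))
    }
  }
  n_trials <- dim(epochs$data)[1]
  t_ms <- epoch_times(epochs)
  starts <- moving_window_starts(spec)

  p2p_hit <- function(chan, thresh) {
    ci <- channel_idx(epochs, chan)
    hit <- rep(FALSE, n_trials)
    for (s in starts) {
      idx <- which(t_ms >= s & t_ms < s + spec$window_ms)
      seg <- matrix(epochs$data[, ci, idx], n_trials, length(idx))
      cols <- asplit(seg, 2)
      rng <- as.vector(do.call(pmax, cols)) - as.vector(do.call(pmin, cols))
      hit <- hit | (rng > thresh)
    }
    hit
  }
  eog <- p2p_hit("VEOG", spec$veog_uv) | p2p_hit("HEOG", spec$heog_uv)

  # absolute rule on baseline-corrected data, one channel at a time to keep
  # the memory footprint flat on large epoch sets
  eeg_ci <- which(!epochs$channel_names %in% c("VEOG", "HEOG"))
  bsi <- window_sample_idx(epochs, c(-200, 0))
  abs_hit <- rep(FALSE, n_trials)
  for (c in eeg_ci) {
    m <- matrix(epochs$data[, c, ], n_trials)
    m <- abs(m - rowMeans(m[, bsi, drop = FALSE]))
    abs_hit <- abs_hit | (as.vector(do.call(pmax, asplit(m, 2))) > spec$abs_uv)
  }

  tibble::tibble(trial_id = epochs$trials$trial_id,
                 eog = eog, abs = abs_hit, rejected = eog | abs_hit)
}

#' Flag rejected trials in an epoch set
#'
#' Sets the `rejected` flag in the trial table; rejected trials are kept for
#' bookkeeping but skipped by downstream feature extraction.
#'
#' @param epochs an [epoch_set()].
#' @param mask logical vector (one per trial) or the tibble returned by
#'   [detect_artifacts()].
#' @return the updated [epoch_set()].
#' @export
apply_rejection <- function(epochs, mask) {
  if (is.data.frame(mask)) mask <- mask$rejected
  if (length(mask) != dim(epochs$data)[1]) {
    stop_ag(sprintf("mask length %d does not match %d trials",
                    length(mask), dim(epochs$data)[1]))
  }
  epochs$trials$rejected <- epochs$trials$rejected | mask
  epochs
}

#' Summarize rejection counts
#'
#' @param flags tibble from [detect_artifacts()].
#' @return list with `n_trials`, `n_rejected` and per-rule counts.
#' @export
rejection_summary <- function(flags) {
  list(n_trials = nrow(flags),
       n_rejected = sum(flags$rejected),
       n_eog = sum(flags$eog),
       n_abs = sum(flags$abs))
}
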