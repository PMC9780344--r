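#' Epoched EEG container
#'
#' An `epoch_set` holds segmented multi-channel EEG as a 3-D voltage array
#' (trials x channels x samples, microvolts) together with its sampling rate,
#' the sample index of stimulus onset, channel labels and a per-trial metadata
#' table. It is the common currency of the whole pipeline.
#'
#' @param data numeric 3-D array, trials x channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param onset_index 1-based sample index of stimulus (cue) onset, i.e. the
#'   sample at time 0 ms.
#' @param channel_names character vector of unique channel labels (10-10
#'   nomenclature plus `"VEOG"`, `"HEOG"`).
#' @param trials data frame with one row per trial and columns
#'   `participant_id`, `trial_id`, `cue_present`, `cue_side`, `cue_field`,
#'   `cue_type`, `report`, `rejected`.
#' @param validate check invariants (finite voltages on non-rejected trials,
#'   unique channels, aligned dimensions). Disable only for trusted internal
#'   construction.
#' @return an object of class `epoch_set`.
#' @examples
#' es <- epoch_set(array(0, c(2, 1, 100)), fs = 100, onset_index = 26,
#'                 channel_names = "POz", trials = blank_trials(2))
#' epoch_times(es)[1:4]
#' @export
epoch_set <- function(data, fs, onset_index, channel_names, trials,
                      validate = TRUE) {
  trials <- tibble::as_tibble(trials)
  x <- structure(
    list(data = data, fs = fs, onset_index = as.integer(onset_index),
         channel_names = as.character(channel_names), trials = trials),
    class = "epoch_set"
  )
  if (validate) validate_epoch_set(x)
  x
}

trial_columns <- c("participant_id", "trial_id", "cue_present", "cue_side",
                   "cue_field", "cue_type", "report", "rejected")

#' Minimal trial metadata table
#'
#' Convenience constructor for the per-trial metadata of an [epoch_set()],
#' mostly for tests and examples.
#'
#' @param n number of trials.
#' @return a tibble with the required trial columns.
#' @export
blank_trials <- function(n) {
  tibble::tibble(
    participant_id = "s01",
    trial_id = seq_len(n),
    cue_present = TRUE,
    cue_side = "left",
    cue_field = "lower",
    cue_type = "face",
    report = "left",
    rejected = FALSE
  )
}

validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (length(d) != 3) stop_ag("`data` must be a 3-D array (trials x channels x samples)")
  if (!is.numeric(x$fs) || length(x$fs) != 1 || x$fs <= 0) {
    stop_ag("`fs` must be a single positive sampling rate in Hz")
  }
  if (x$onset_index < 1 || x$onset_index > d[3]) {
    stop_ag("`onset_index` must lie within the sample range")
  }
  if (anyDuplicated(x$channel_names)) {
    stop_ag("duplicate channel names are not allowed")
  }
  if (length(x$channel_names) != d[2]) {
    stop_ag(sprintf("%d channel names for %d data channels",
                    length(x$channel_names), d[2]))
  }
  miss <- setdiff(trial_columns, names(x$trials))
  if (length(miss)) stop_ag(paste0("trial table lacks columns: ",
                                   paste(miss, collapse = ", ")))
  if (nrow(x$trials) != d[1]) {
    stop_ag(sprintf("trial table has %d rows for %d data trials",
                    nrow(x$trials), d[1]))
  }
  if (d[1] > 0) {
    keep <- !x$trials$rejected
    if (any(keep) && !all(is.finite(x$data[keep, , , drop = FALSE]))) {
      stop_ag("non-finite voltages on non-rejected trials")
    }
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  t <- epoch_times(x)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms (onset at sample %d); %d rejected trial(s)\n",
              min(t), max(t), x$onset_index, sum(x$trials$rejected)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Per-sample time vector of an epoch set
#'
#' @param epochs an [epoch_set()].
#' @return numeric vector of times in ms relative to stimulus onset.
#' @export
epoch_times <- function(epochs) {
  (seq_len(dim(epochs$data)[3]) - epochs$onset_index) * 1000 / epochs$fs
}

#' Analysis time window
#'
#' Windows are in milliseconds relative to stimulus onset and follow the
#' half-open convention: a sample at time t belongs to the window when
#' `start_ms <= t < end_ms`, so adjacent windows tile without double-counting.
#'
#' @param start_ms,end_ms window endpoints in ms; `start_ms < end_ms`.
#' @return a `time_window` object.
#' @examples
#' time_window(150, 250) # the VAN analysis window
#' @export
time_window <- function(start_ms, end_ms) {
  if (!is.numeric(start_ms) || !is.numeric(end_ms) || start_ms >= end_ms) {
    stop_ag("`start_ms` must be strictly less than `end_ms`")
  }
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "time_window")
}

as_time_window <- function(w) {
  if (inherits(w, "time_window")) return(w)
  if (is.numeric(w) && length(w) == 2) return(time_window(w[1], w[2]))
  stop_ag("expected a time_window or a numeric pair c(start_ms, end_ms)")
}

window_sample_idx <- function(epochs, window) {
  window <- as_time_window(window)
  t <- epoch_times(epochs)
  idx <- which(t >= window$start_ms & t < window$end_ms)
  if (length(idx) == 0 || window$start_ms < min(t) || window$end_ms > max(t) + 1000 / epochs$fs) {
    stop_ag(sprintf("window [%g, %g) ms lies (partly) outside the epoch span [%g, %g] ms",
                    window$start_ms, window$end_ms, min(t), max(t)))
  }
  idx
}

channel_idx <- function(epochs, channels) {
  i <- match(channels, epochs$channel_names)
  if (anyNA(i)) {
    stop_ag(paste0("unknown channel(s): ",
                   paste(channels[is.na(i)], collapse = ", ")))
  }
  i
}

#' Per-trial mean voltage over a time window and channel set
#'
#' Averages the voltage over all samples falling in the half-open window and
#' over the listed channels, separately for every trial. This is the primitive
#' behind ERP amplitude measures such as the 150-250 ms VAN-window mean.
#'
#' @param epochs an [epoch_set()].
#' @param window a [time_window()] or numeric pair in ms.
#' @param channels character vector of channel names to average over.
#' @return numeric vector with one value (microvolts) per trial.
#' @examples
#' es <- epoch_set(array(-5, c(3, 2, 100)), 100, 26, c("Oz", "POz"),
#'                 blank_trials(3))
#' window_mean(es, c(0, 100), c("Oz", "POz"))
#' @export
window_mean <- function(epochs, window, channels) {
  si <- window_sample_idx(epochs, window)
  ci <- channel_idx(epochs, channels)
  seg <- epochs$data[, ci, si, drop = FALSE]
  apply(seg, 1, mean)
}

# Subset trials of an epoch_set (keeps all channels/samples).
epochs_subset <- function(epochs, keep) {
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$onset_index,
            epochs$channel_names, epochs$trials[keep, , drop = FALSE],
            validate = FALSE)
}
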