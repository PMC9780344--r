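# Trial-level feature table: prestimulus alpha power and phase, VAN-window
# amplitude, perception labels, tercile conditions.

#' Analysis specification
#'
#' Fixes the spatiotemporal measurement points of the trial-level analysis:
#' the occipitoparietal ROI over which 8-12 Hz log power (at -250 ms) and the
#' 150-250 ms VAN-window amplitude are averaged; the single electrode (POz),
#' frequency (10 Hz) and time (-250 ms) at which phase is measured; the
#' minimum retained-trial count per perception condition below which a
#' participant is excluded; and the medial electrodes used for topography
#' contrasts. -250 ms is the midpoint of the last 500-ms alpha analysis
#' window containing prestimulus activity only.
#'
#' @param roi occipitoparietal ROI channels.
#' @param band alpha band limits (Hz), inclusive.
#' @param power_time_ms power measurement time (ms).
#' @param phase_channel,phase_freq,phase_time_ms phase measurement point.
#' @param van_window VAN analysis window (ms, half-open).
#' @param min_trials per-condition minimum retained-trial count.
#' @param topo_channels electrodes for topography contrasts.
#' @return an `analysis_spec`.
#' @export
analysis_spec <- function(roi = c("POz", "PO3", "PO4", "PO7", "PO8", "Oz",
                                  "O1", "O2", "P3", "P4"),
                          band = c(8, 12),
                          power_time_ms = -250,
                          phase_channel = "POz",
                          phase_freq = 10,
                          phase_time_ms = -250,
                          van_window = c(150, 250),
                          min_trials = 30,
                          topo_channels = c("POz", "CPz", "FCz")) {
  structure(list(roi = roi, band = band, power_time_ms = power_time_ms,
                 phase_channel = phase_channel, phase_freq = phase_freq,
                 phase_time_ms = phase_time_ms,
                 van_window = as_time_window(van_window),
                 min_trials = min_trials, topo_channels = topo_channels),
            class = "analysis_spec")
}

#' Label trial-level perception and retention
#'
#' Perceived = cue present and the reported side matches the cue side;
#' not-perceived = cue present and reported absent. Cue-present trials with a
#' wrong-side report are excluded (it is unclear whether the cue was truly
#' perceived), as are all cue-absent trials.
#'
#' @param trials trial metadata table (as in an [epoch_set()]).
#' @return the table with added columns `perceived` (0/1, NA when excluded)
#'   and `retained` (logical; also requires `rejected == FALSE`).
#' @export
label_perception <- function(trials) {
  ok_report <- trials$report %in% c("left", "right", "absent")
  if (!all(ok_report)) {
    stop_ag(paste0("malformed report values: ",
                   paste(unique(trials$report[!ok_report]), collapse = ", ")))
  }
  trials |>
    dplyr::mutate(
      perceived = dplyr::case_when(
        !.data$cue_present ~ NA_integer_,
        .data$report == .data$cue_side ~ 1L,
        .data$report == "absent" ~ 0L,
        TRUE ~ NA_integer_   # wrong-side report
      ),
      retained = !is.na(.data$perceived) & !.data$rejected
    )
}

#' Exclude participants with too few trials per condition
#'
#' Drops participants with fewer than `min_trials` retained perceived or
#' not-perceived trials.
#'
#' @param features a labeled feature/trial table with `participant`
#'   (or `participant_id`) and `perceived` columns.
#' @param min_trials threshold (a count of `min_trials` is kept).
#' @return the filtered table; excluded participants are recorded in the
#'   `"excluded"` attribute (a tibble with per-condition counts).
#' @export
exclude_participants <- function(features, min_trials = 30) {
  if (nrow(features) == 0) stop_ag("empty feature table")
  pid <- if ("participant" %in% names(features)) "participant" else "participant_id"
  counts <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pid))) |>
    dplyr::summarise(n_perceived = sum(.data$perceived == 1),
                     n_not_perceived = sum(.data$perceived == 0),
                     .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_perceived < min_trials |
                    .data$n_not_perceived < min_trials)
  drop <- counts[[pid]][counts$excluded]
  out <- features[!features[[pid]] %in% drop, , drop = FALSE]
  attr(out, "excluded") <- counts[counts$excluded, , drop = FALSE]
  out
}

# Mean log power over the alpha band and ROI at the power time (direct path:
# only band frequencies x one analysis time are computed).
roi_band_power <- function(epochs, spec) {
  freqs <- seq(spec$band[1], spec$band[2])
  tfr <- tfr_transform(epochs, tfr_spec(freqs = freqs, times = spec$power_time_ms),
                       channels = spec$roi, method = "direct")
  if (!all(tfr$valid)) stop_ag("alpha power window does not fit inside the epoch")
  lp <- log_power(tfr)                   # trials x roi x freqs x 1
  apply(lp, 1, mean)
}

phase_at_point <- function(epochs, spec) {
  tfr <- tfr_transform(epochs, tfr_spec(freqs = spec$phase_freq,
                                        times = spec$phase_time_ms),
                       channels = spec$phase_channel, method = "direct")
  if (!all(tfr$valid)) stop_ag("phase window does not fit inside the epoch")
  as.vector(phase_angles(tfr))
}

z_by_participant <- function(x, participant) {
  out <- rep(NA_real_, length(x))
  for (p in unique(participant)) {
    i <- which(participant == p)
    if (length(i) < 2 || stats::sd(x[i]) == 0) {
      stop_ag(sprintf("cannot z-score participant '%s': fewer than two distinct values", p))
    }
    out[i] <- (x[i] - mean(x[i])) / stats::sd(x[i])
  }
  out
}

#' Build the trial-level feature table
#'
#' For every retained trial (cue-present, not artifact-rejected, report either
#' correct-side or absent), measures: log alpha power (natural log, averaged
#' over 8-12 Hz and the ROI at -250 ms), alpha phase (10 Hz, POz, -250 ms),
#' and the VAN-window ERP amplitude (ROI mean over 150-250 ms). Power and VAN
#' amplitude are then z-scored within participant over the retained trials,
#' and trials are split into per-participant power terciles.
#'
#' @param epochs a baseline-corrected [epoch_set()].
#' @param spec an [analysis_spec()].
#' @param min_trials participant exclusion threshold; `NULL` to skip
#'   exclusion.
#' @return a `trial_features` tibble: `participant`, `trial`, `power`,
#'   `power_z`, `phase`, `van`, `van_z`, `tercile`, `perceived`, `cue_field`,
#'   `cue_side`. Participant exclusions are kept in the `"excluded"`
#'   attribute.
#' @export
extract_features <- function(epochs, spec = analysis_spec(),
                             min_trials = spec$min_trials) {
  labeled <- label_perception(epochs$trials)
  keep <- which(labeled$retained)
  if (length(keep) == 0) stop_ag("no trials retained after filtering")
  sub <- epochs_subset(epochs, keep)

  feat <- tibble::tibble(
    participant = labeled$participant_id[keep],
    trial = labeled$trial_id[keep],
    power = roi_band_power(sub, spec),
    phase = phase_at_point(sub, spec),
    van = window_mean(sub, spec$van_window, spec$roi),
    perceived = labeled$perceived[keep],
    cue_field = labeled$cue_field[keep],
    cue_side = labeled$cue_side[keep]
  )
  if (!is.null(min_trials)) feat <- exclude_participants(feat, min_trials)
  if (nrow(feat) == 0) stop_ag("all participants excluded")
  feat$power_z <- z_by_participant(feat$power, feat$participant)
  feat$van_z <- z_by_participant(feat$van, feat$participant)
  feat <- tercile_split(feat)
  feat <- feat[, c("participant", "trial", "power", "power_z", "phase",
                   "van", "van_z", "tercile", "perceived", "cue_field",
                   "cue_side")]
  class(feat) <- c("trial_features", class(feat))
  feat
}

#' Split trials into per-participant power terciles
#'
#' Trials are sorted by ascending prestimulus alpha power within participant
#' (ties broken by trial id, so the split is deterministic). With remainder
#' `r = n %% 3`, the low tercile takes one extra trial when `r >= 1` and the
#' mid tercile when `r == 2`, so low/high sizes never differ by more than 1.
#'
#' @param features a feature table with `participant`, `trial`, `power`.
#' @return the table with a `tercile` factor (`low`, `mid`, `high`).
#' @export
tercile_split <- function(features) {
  lab <- rep(NA_character_, nrow(features))
  for (p in unique(features$participant)) {
    i <- which(features$participant == p)
    n <- length(i)
    if (n < 3) stop_ag(sprintf("participant '%s' has %d trials; need >= 3 for terciles", p, n))
    ord <- i[order(features$power[i], features$trial[i])]
    r <- n %% 3
    n_low <- n %/% 3 + (r >= 1)
    n_mid <- n %/% 3 + (r == 2)
    lab[ord] <- rep(c("low", "mid", "high"),
                    c(n_low, n_mid, n - n_low - n_mid))
  }
  features$tercile <- factor(lab, levels = c("low", "mid", "high"))
  features
}

#' Condition-averaged ERPs
#'
#' Averages the voltage traces across trials within each level of a grouping
#' column of the feature table (default the power tercile), per channel, and
#' extracts the VAN-window ROI mean per condition.
#'
#' @param epochs the (baseline-corrected) [epoch_set()] the features came
#'   from.
#' @param features a `trial_features` table.
#' @param spec an [analysis_spec()].
#' @param by feature column defining the conditions.
#' @return a tibble `condition, channel, time_ms, amplitude` with the
#'   per-condition VAN-window ROI means in attribute `"van_mean"`.
#' @export
condition_erp <- function(epochs, features, spec = analysis_spec(),
                          by = "tercile") {
  conds <- unique(as.character(features[[by]]))
  if (nrow(features) == 0 || length(conds) == 0) {
    stop_ag("no trials in any condition")
  }
  t_ms <- epoch_times(epochs)
  rows_for <- function(cond) {
    ids <- features$trial[as.character(features[[by]]) == cond]
    match(ids, epochs$trials$trial_id)
  }
  out <- purrr::map_dfr(conds, function(cond) {
    i <- rows_for(cond)
    if (length(i) == 0) stop_ag(sprintf("condition '%s' has no trials", cond))
    avg <- apply(epochs$data[i, , , drop = FALSE], c(2, 3), mean)
    tibble::tibble(
      condition = cond,
      channel = rep(epochs$channel_names, each = length(t_ms)),
      time_ms = rep(t_ms, times = length(epochs$channel_names)),
      amplitude = as.vector(t(avg))
    )
  })
  si <- window_sample_idx(epochs, spec$van_window)
  ci <- channel_idx(epochs, spec$roi)
  van_mean <- vapply(conds, function(cond) {
    i <- rows_for(cond)
    mean(epochs$data[i, ci, si])
  }, numeric(1))
  attr(out, "van_mean") <- van_mean
  out
}

#' Low-minus-high VAN-window topography by cue field
#'
#' For each participant, cue field (upper/lower) and topography electrode,
#' averages the VAN-window voltage separately over low- and high-power
#' tercile trials and returns the low-minus-high difference.
#'
#' @param epochs the [epoch_set()] the features came from.
#' @param features a `trial_features` table.
#' @param spec an [analysis_spec()].
#' @return tibble `participant, cue_field, channel, value` (microvolts).
#' @export
diff_topography <- function(epochs, features, spec = analysis_spec()) {
  si <- window_sample_idx(epochs, spec$van_window)
  ci <- channel_idx(epochs, spec$topo_channels)
  cells <- features |>
    dplyr::filter(.data$tercile %in% c("low", "high"),
                  .data$cue_field %in% c("upper", "lower"))
  out <- cells |>
    dplyr::group_by(.data$participant, .data$cue_field, .data$tercile) |>
    dplyr::group_modify(function(d, key) {
      i <- match(d$trial, epochs$trials$trial_id)
      m <- apply(epochs$data[i, ci, si, drop = FALSE], 2, mean)
      tibble::tibble(channel = spec$topo_channels, amp = m)
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "tercile", values_from = "amp") |>
    dplyr::mutate(value = .data$low - .data$high) |>
    dplyr::select("participant", "cue_field", "channel", "value")
  if (anyNA(out$value)) {
    stop_ag("some participant x field cells have no low- or high-tercile trials")
  }
  out
}
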