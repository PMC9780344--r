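# ggplot2 displays for the main result types.

#' Plot condition-averaged ERP traces
#'
#' @param erp tibble from [condition_erp()].
#' @param channels channels to facet (default the first four present).
#' @param xlim time range in ms.
#' @return a ggplot object.
#' @export
plot_condition_erp <- function(erp, channels = NULL, xlim = c(-200, 600)) {
  channels <- channels %||% head(unique(erp$channel), 4)
  erp |>
    dplyr::filter(.data$channel %in% channels,
                  .data$time_ms >= xlim[1], .data$time_ms <= xlim[2]) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_ms, .data$amplitude,
                                 colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot per-participant preferred phases by condition
#'
#' Each arrow is one participant's bootstrap preferred phase; arrow length is
#' the ITPC of the bootstrap iteration means.
#'
#' @param x a `phase_comparison` from [compare_preferred_phase()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot phase_comparison
#' @export
autoplot.phase_comparison <- function(x, ...) {
  d <- x$by_participant |>
    tidyr::pivot_longer(c("perceived", "not_perceived"),
                        names_to = "condition", values_to = "phase")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = 1,
                                  colour = .data$condition)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$phase, yend = 0),
                          arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = seq(-pi / 2, pi, pi / 2),
                                labels = c("-90°", "0°", "90°", "180°")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Coefficient plot for a structural fit
#'
#' Point estimates with cluster-bootstrap 95% intervals for both model
#' stages.
#'
#' @param x a `structural_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot structural_fit
#' @export
autoplot.structural_fit <- function(x, ...) {
  tidy(x) |>
    ggplot2::ggplot(ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::labs(x = "coefficient (95% cluster-bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Binned phase dependence of the VAN amplitude
#'
#' Mean z-scored VAN amplitude in phase bins, split by power tercile; a
#' quick visual check of the power-gated phase effect.
#'
#' @param x a `trial_features` table.
#' @param bins number of phase bins.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot trial_features
#' @export
autoplot.trial_features <- function(x, bins = 12, ...) {
  x |>
    dplyr::mutate(phase_bin = cut(.data$phase, seq(-pi, pi, length.out = bins + 1),
                                  include.lowest = TRUE)) |>
    dplyr::group_by(.data$tercile, .data$phase_bin) |>
    dplyr::summarise(van_z = mean(.data$van_z),
                     phase_mid = mean(.data$phase), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$phase_mid, .data$van_z,
                                 colour = .data$tercile)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "prestimulus alpha phase (rad)",
                  y = "VAN-window amplitude (z)",
                  colour = "power tercile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
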