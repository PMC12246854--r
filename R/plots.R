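#' Plot an EDA series
#'
#' Conductance over time with repaired (flagged) samples highlighted and
#' event marks as vertical lines.
#'
#' @param object an [eda_series].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot eda_series
#' @export
autoplot.eda_series <- function(object, ...) {
  ev <- attr(object, "events")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$conductance_us)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$artifact),
                        colour = "red", size = 0.5) +
    ggplot2::labs(x = "time (s)", y = expression(paste("conductance (", mu, "S)")),
                  title = attr(object, "participant_id")) +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 linetype = "dashed", colour = "steelblue",
                                 alpha = 0.6)
  }
  p
}

#' Plot group-mean cortisol trajectories
#'
#' Mean concentration per group over the five sampling points, with
#' standard-error ribbons — the standard recovery-comparison figure.
#'
#' @param panel a [cortisol_panel][read_cortisol_csv].
#' @return a ggplot.
#' @export
plot_cortisol_trajectories <- function(panel) {
  gm <- cortisol_group_means(panel)
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$minutes, y = .data$nmol_per_l,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$nmol_per_l - .data$sem,
                                      ymax = .data$nmol_per_l + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minutes from stress end", y = "cortisol (nmol/L)") +
    ggplot2::theme_minimal()
}

#' Plot a scalp-coupling-index report
#'
#' Per-channel SCI with the rejection threshold; rejected channels in red.
#'
#' @param object an `sci_report` (see [sci_report()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sci_report
#' @export
autoplot.sci_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::arrange(as_tibble(object), .data$sci)
  df$channel_id <- factor(df$channel_id, levels = df$channel_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_id, y = .data$sci,
                                   fill = .data$keep)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "scalp coupling index", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot LIR by stage
#'
#' Distribution of the laterality index per stage across participants,
#' one facet per channel pair; positive values are right-dominant.
#'
#' @param lir a [lir_table()].
#' @param stages stages to show (default baseline, stress, sound).
#' @return a ggplot.
#' @export
plot_lir <- function(lir, stages = c("baseline", "stress", "sound")) {
  df <- dplyr::filter(as_tibble(lir), .data$stage %in% stages)
  df$pair <- paste0("[", df$right_channel, ", ", df$left_channel, "]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$lir)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(y = "laterality index (right - left)/(right + left)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
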