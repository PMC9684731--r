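#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Welch power spectrum
#'
#' @param object A `psd_tbl` from [welch_psd()].
#' @param log_power Plot power on a log10 scale (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_tbl <- function(object, log_power = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency,
                                            y = .data$power)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot relative band power
#'
#' @param object A `band_power_tbl` from [band_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_power_tbl <- function(object, ...) {
  object$band <- factor(object$band, levels = object$band)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$band,
                                       y = .data$relative_power_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Relative power (%)") +
    ggplot2::theme_minimal()
}

#' Plot a coherence spectrum
#'
#' Draws the magnitude-squared coherence with the 95% zero-coherence
#' confidence threshold as a dashed line.
#'
#' @param object A `coherence_tbl` from [msc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency,
                                       y = .data$coherence)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "confidence_level_095"),
                        linetype = "dashed", color = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence") +
    ggplot2::theme_minimal()
}

#' Maze learning curve
#'
#' Group mean +/- SEM of total errors per block.
#'
#' @param maze_blocks A block totals table (e.g. `maze_blocks` from
#'   [run_pipeline()]) with columns `group`, `block`, `total`.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(maze_blocks) {
  need <- c("group", "block", "total")
  if (!all(need %in% names(maze_blocks))) {
    abort_data("`maze_blocks` must have columns group, block, total")
  }
  summ <- maze_blocks |>
    dplyr::group_by(.data$group, .data$block) |>
    dplyr::summarise(mean_total = mean(.data$total),
                     sem = stats::sd(.data$total) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$block, y = .data$mean_total,
                                     color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_total - .data$sem,
                                          ymax = .data$mean_total + .data$sem)) +
    ggplot2::labs(x = "Block (3 runs)", y = "Total errors (RME + WME)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
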