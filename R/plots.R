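#' Plot an extracted-ion chromatogram
#'
#' Intensity against retention time, with optional baseline and apex
#' annotations as produced by the peak measurement chain.
#'
#' @param object A `qc_eic`.
#' @param baseline Optional baseline level to draw.
#' @param apex_rt Optional apex RT to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_eic <- function(object, baseline = NULL, apex_rt = NULL, ...) {
  d <- tibble::tibble(rt = object$rt, intensity = object$intensity)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "retention time [s]", y = "intensity [counts]",
                  title = if (!is.na(object$target_mz))
                    sprintf("EIC m/z %.4f (+/-%g ppm)", object$target_mz,
                            object$ppm) else "EIC") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, colour = "darkgreen",
                                 linetype = 2)
  }
  if (!is.null(apex_rt)) {
    p <- p + ggplot2::geom_vline(xintercept = apex_rt, colour = "firebrick",
                                 linetype = 3)
  }
  p
}

#' Control chart of a stored metric
#'
#' Time series of normalised intensity, RT deviation or mass error per
#' internal standard from an exported internal-standard table, with the
#' univariate control limits as horizontal lines.
#'
#' @param table Tibble from [export_internal_standard_table()].
#' @param metric `"normalised_intensity"`, `"rt_deviation_s"` or
#'   `"mass_error_ppm"`.
#' @param cfg A [qc_config()] supplying the limits.
#' @return A ggplot.
#' @export
plot_control_chart <- function(table,
                               metric = c("normalised_intensity",
                                          "rt_deviation_s", "mass_error_ppm"),
                               cfg = qc_config()) {
  metric <- match.arg(metric)
  limits <- switch(metric,
                   normalised_intensity = cfg$intensity_limits,
                   rt_deviation_s = c(-1, 1) * cfg$rt_deviation_limit,
                   mass_error_ppm = c(-1, 1) * cfg$mass_error_limit)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$acquired_at,
                                      y = .data[[metric]],
                                      colour = .data$compound_id)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = limits, linetype = 2) +
    ggplot2::labs(x = NULL, y = metric, colour = "internal standard") +
    ggplot2::theme_minimal()
}

#' Contribution plot for a multivariate alarm
#'
#' Per-feature score-times-loading contributions for one block of an
#' `mspc_result`, the standard diagnostic for which internal standards (or
#' pairs) drive an out-of-control signal.
#'
#' @param object An `mspc_result`.
#' @param block Block to plot (default: first flagged, else first available).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mspc_result <- function(object, block = NULL, ...) {
  if (nrow(object$contributions) == 0) abort("result holds no block models")
  block <- block %||% (if (length(object$flagged_blocks))
    object$flagged_blocks[1] else object$blocks$block[1])
  d <- object$contributions[object$contributions$block == block, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$contribution,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(title = paste0("contributions: ", block, " block"),
                  x = NULL, y = "score x loading") +
    ggplot2::theme_minimal()
}
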