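# Forest and funnel rendering. Each renderer returns both the ggplot
# object and the plain coordinate table it was drawn from, so plotted
# numbers stay testable.

#' Render a forest plot
#'
#' One row per study (square at the OR, horizontal bar for the 95% CI),
#' a diamond for the pooled estimate at the bottom and a vertical
#' reference line at OR = 1, on a log-scaled axis.
#'
#' @param pooled A `pooled_result`.
#' @param effects The matching [study_effects()] data frame.
#' @return List with `plot` (ggplot) and `coords` (the coordinate table;
#'   the pooled diamond is the row with `role == "pooled"`).
#' @export
render_forest <- function(pooled, effects) {
  coords <- rbind(
    data.frame(study_label = effects$study_label, or = effects$or,
               ci_low = effects$ci_low, ci_high = effects$ci_high,
               role = "study", stringsAsFactors = FALSE),
    data.frame(study_label = paste0("Pooled (", pooled$model, ")"),
               or = pooled$or, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
               role = "pooled", stringsAsFactors = FALSE))
  coords$y <- rev(seq_len(nrow(coords)))
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$or, y = .data$y)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$role, size = .data$role)) +
    ggplot2::scale_shape_manual(values = c(study = 15, pooled = 18), guide = "none") +
    ggplot2::scale_size_manual(values = c(study = 3, pooled = 5), guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(breaks = coords$y, labels = coords$study_label) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
  list(plot = p, coords = coords)
}

#' Render a funnel plot
#'
#' Scatter of per-study log OR against its standard error with the SE
#' axis increasing downward, a vertical centre line at the pooled log OR
#' and pseudo-95% guide lines.
#'
#' @param fd A `funnel_data` from [funnel_data()].
#' @return List with `plot` (ggplot) and `coords` (the study points).
#' @export
render_funnel <- function(fd) {
  stopifnot(inherits(fd, "funnel_data"))
  p <- ggplot2::ggplot(fd$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = fd$guides, ggplot2::aes(x = .data$lo, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_line(data = fd$guides, ggplot2::aes(x = .data$hi, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_vline(xintercept = fd$centre, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log OR", y = "Standard error of log OR") +
    ggplot2::theme_minimal()
  list(plot = p, coords = fd$points)
}
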