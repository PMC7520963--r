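# ggplot2 views of the result objects.

#' Plot the four score components
#'
#' @param object A `plast_score` from [compute_score()] or
#'   [score_assembly()].
#' @param ... Unused.
#' @return A ggplot: one bar per component (each contributes up to 25
#'   score points), annotated with the composite score.
#' @method autoplot plast_score
#' @export
autoplot.plast_score <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$contribution)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::ylim(0, 25) +
    ggplot2::labs(
      title = sprintf("Assembly score: %.2f / 100", object$score),
      x = NULL, y = "score points (max 25 each)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot run-to-run score consistency
#'
#' @param object A `consistency_report` from [compare_runs()].
#' @param ... Unused.
#' @return A ggplot scatter of first-run vs second-run scores; datasets
#'   that failed in one run are omitted (they have no coordinate).
#' @method autoplot consistency_report
#' @export
autoplot.consistency_report <- function(object, ...) {
  d <- dplyr::filter(object$datasets, .data$both_succeeded)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score_run1, y = .data$score_run2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "score, run 1", y = "score, run 2") +
    ggplot2::theme_minimal()
}

#' Plot the F1 landscape of a cutoff calibration
#'
#' @param object A `cutoff_calibration` from [select_cutoffs()].
#' @param ... Unused.
#' @return A ggplot tile map of F1 over the cutoff grid with the selected
#'   pair marked.
#' @method autoplot cutoff_calibration
#' @export
autoplot.cutoff_calibration <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(
    x = .data$min_total_len / 1000, y = .data$min_ir_len / 1000,
    fill = .data$f1
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = object$best,
      ggplot2::aes(x = .data$min_total_len / 1000, y = .data$min_ir_len / 1000),
      colour = "red", inherit.aes = FALSE
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "minimum assembly length (kbp)", y = "minimum IR length (kbp)",
      fill = "F1"
    ) +
    ggplot2::theme_minimal()
}
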