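#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training curves
#'
#' Loss and validation-AUC trajectories per epoch; fine-tuning epochs
#' additionally show the adaptive dual-loss weight k.
#'
#' @param object A trained `mimoscan_predictor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mimoscan_predictor <- function(object, ...) {
  h <- tidy(object)
  h$row <- seq_len(nrow(h))
  long <- tidyr::pivot_longer(
    h, dplyr::any_of(c("loss_bce", "loss_mse", "k", "val_auc")),
    names_to = "series", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$row, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a screening trajectory
#'
#' Best oracle-confirmed ddG versus cumulative oracle calls, with the
#' objective threshold as a reference line.
#'
#' @param object A `mimoscan_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mimoscan_screen <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(.data$n_sampled, .data$best_observed)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(
      x = "oracle observations", y = "best observed ddG (kcal/mol)",
      title = sprintf("%s screening of %s", object$policy$strategy,
                      object$parent)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of mutant values (position x residue)
#'
#' The classic deep-mutational-scanning layout: substituted residue on
#' the y axis, peptide position on the x axis, fill = ddG. Wild-type
#' cells are blank.
#'
#' @param mutants Mutant tibble with a value column.
#' @param value Column to plot (default `"ddg_pred"`).
#' @return A ggplot.
#' @export
plot_mutant_heatmap <- function(mutants, value = "ddg_pred") {
  stopifnot(value %in% names(mutants))
  ggplot2::ggplot(mutants, ggplot2::aes(
    factor(.data$position), .data$to_res,
    fill = .data[[value]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev(amino_acids)) +
    ggplot2::labs(x = "position", y = "substituted residue",
                  fill = "ddG\n(kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot strategy-comparison curves
#'
#' Mean precision and recall versus the number of oracle samples, one
#' line per acquisition strategy.
#'
#' @param bench A [benchmark_strategies()] result.
#' @param grid Optional common grid of sample counts (see
#'   [benchmark_curves()]).
#' @return A ggplot.
#' @export
plot_benchmark <- function(bench, grid = NULL) {
  curves <- benchmark_curves(bench, grid)
  long <- tidyr::pivot_longer(curves, c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$n_samples, .data$value,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "oracle samples used for fine-tuning", y = NULL) +
    ggplot2::theme_minimal()
}
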