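#' Parity plot of calculated vs experimental log solubility
#'
#' Scatter of predicted against experimental `ln x`, one point per record,
#' coloured by solute, with the identity line.
#'
#' @param predictions Tibble with columns `solute`, `x`, `x_pred`.
#' @return A ggplot object.
#' @export
plot_parity <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = log(.data$x), y = log(.data$x_pred),
                               colour = .data$solute)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "experimental ln x", y = "calculated ln x",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Solubility-curve plot over temperature
#'
#' Predicted mole-fraction solubility against temperature, one panel per
#' solvent; experimental points are overlaid when an `x` column is present.
#'
#' @param predictions Tibble with columns `solvent`, `T_K`, `x_pred` and
#'   optionally `x`.
#' @return A ggplot object.
#' @export
plot_solubility_curves <- function(predictions) {
  p <- ggplot2::ggplot(predictions, ggplot2::aes(x = .data$T_K)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_pred), colour = "#2166ac") +
    ggplot2::facet_wrap(~solvent, scales = "free_y") +
    ggplot2::labs(x = "T (K)", y = "mole fraction x") +
    ggplot2::theme_minimal()
  if ("x" %in% names(predictions)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$x), colour = "black",
                                 size = 1.3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-system evaluation report
#'
#' Bar chart of per-system RMSLE (paper convention), grouped by solute.
#'
#' @param object An `sb_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sb_report <- function(object, ...) {
  ggplot2::ggplot(object$systems,
                  ggplot2::aes(x = .data$solvent, y = .data$rmsle_paper,
                               fill = .data$solute)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~solute, scales = "free_x") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "RMSLE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
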