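# ggplot2 views of the per-site analyses and the fitted consensus model.

#' Plot a per-site fluctuation profile
#'
#' @param msf Tibble from [mean_square_fluctuations()].
#' @return A ggplot object (residue number vs mean-square fluctuation, one
#'   panel per chain).
#' @export
plot_fluctuation_profile <- function(msf) {
  ggplot2::ggplot(msf, ggplot2::aes(x = .data$resno, y = .data$msf)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue number",
                  y = expression(paste("mean-square fluctuation (", ring(A)^2, ")"))) +
    ggplot2::theme_minimal()
}

#' Plot a residue cross-correlation matrix
#'
#' @param correlation N x N matrix from [cross_correlation()].
#' @return A ggplot heatmap, blue (anti-correlated) to red (correlated).
#' @export
plot_correlation_matrix <- function(correlation) {
  df <- tidyr::expand_grid(i = seq_len(nrow(correlation)),
                           j = seq_len(ncol(correlation)))
  df$c <- as.vector(t(correlation))  # expand_grid varies j fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "C") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue index", y = "residue index") +
    ggplot2::theme_minimal()
}

#' Plot a per-site deformation-energy profile
#'
#' @param deformation Tibble from [deformation_energy()].
#' @return A ggplot object.
#' @export
plot_deformation_profile <- function(deformation) {
  ggplot2::ggplot(deformation,
                  ggplot2::aes(x = .data$resno, y = .data$deformation)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue number", y = "relative deformation energy") +
    ggplot2::theme_minimal()
}

#' Cross-validation scatter for a fitted consensus model
#'
#' Out-of-fold predictions against experimental ddG, with the identity line.
#'
#' @param object A `consensus_model`.
#' @param data The training tibble the model was fitted on (for `ddg_exp`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_model
#' @export
autoplot.consensus_model <- function(object, data, ...) {
  df <- tibble::tibble(observed = data$ddg_exp,
                       predicted = object$cv_predictions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "experimental ddG (kcal/mol)",
                  y = "out-of-fold predicted ddG (kcal/mol)") +
    ggplot2::theme_minimal()
}
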