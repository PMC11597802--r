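# ggplot2 diagnostics for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.grey_result <- function(object, ...) {
  df <- object$degrees |>
    tidyr::pivot_longer(c("gamma_unweighted", "gamma_weighted"),
                        names_to = "scheme", values_to = "gamma") |>
    dplyr::mutate(scheme = sub("gamma_", "", .data$scheme))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$entity, -.data$gamma),
    y = .data$gamma, fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "grey relational degree",
                  title = sprintf("Grey relational ranking (R² = %.2f)",
                                  object$r2_agreement)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ll2_fit <- function(object, max_conc = NULL, ...) {
  max_conc <- max_conc %||% (2 * object$e)
  grid <- tibble::tibble(concentration = seq(1e-6, max_conc, length.out = 200))
  grid$p <- predict(object, grid$concentration)
  ggplot2::ggplot(grid, ggplot2::aes(.data$concentration, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$e, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "concentration (mM)", y = "mortality probability",
                  title = sprintf("Log-logistic fit: LC50 = %.1f, slope = %.2f",
                                  object$e, object$b)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.soft_threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(.data$power, .data$fit_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$beta, linetype = 3) +
    ggplot2::labs(x = "soft-threshold power β",
                  y = "scale-free fit index",
                  title = sprintf("Chosen β = %d", object$beta)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sample_qc <- function(object, ...) {
  varexp <- attr(object$pca, "var_explained")
  ggplot2::ggplot(object$pca, ggplot2::aes(.data$PC1, .data$PC2,
                                           label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * varexp[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * varexp[2]),
      title = "Sample PCA") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param mt Long tibble from [module_trait_correlation()].
#' @return A ggplot object: modules x traits tiles coloured by r, labelled
#'   "r (p)" as is conventional for module-trait displays.
#' @export
plot_module_trait <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(.data$trait, .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1e)", .data$r, .data$p)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Module-trait correlation") +
    ggplot2::theme_minimal()
}
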