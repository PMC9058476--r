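# ggplot2 displays for the main result types.

#' Correlation heatmap with block-aware ordering
#'
#' @param object A `correlation_summary`.
#' @param cut Threshold used both for the block-contiguous ordering and the
#'   outline shading of high-correlation cells.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_summary <- function(object, cut = 0.9, ...) {
  ord <- find_blocks(object$Omega, cut)$ordering
  long <- tibble::as_tibble(as.data.frame.table(object$Omega,
                                                responseName = "omega"))
  names(long)[1:2] <- c("alpha", "beta")
  long$alpha <- factor(long$alpha, levels = ord)
  long$beta <- factor(long$beta, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(.data$alpha, .data$beta,
                                     fill = .data$omega)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = long[long$omega >= cut, ],
                       colour = "grey20", linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", midpoint = 0,
                                  limits = c(-1, 1), name = "Ω") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Method correlations (blocks at Ω ≥ %g)",
                                  cut)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Scree plot of a correlation-matrix PCA
#'
#' @param object An `nac_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nac_pca <- function(object, ...) {
  df <- tibble::tibble(component = seq_len(object$V),
                       eigenvalue = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Principal component",
                  y = "Eigenvalue (variables' worth of correlation)",
                  title = sprintf("%s-matrix PCA: MPC explains %.1f%%",
                                  object$kind,
                                  object$percent_explained[1])) +
    ggplot2::theme_minimal()
}

#' Confluence-score bar chart
#'
#' @param object A `confluence_scores`.
#' @param ... Unused.
#' @return A ggplot showing Omega(alpha, phi) per method, superdelegate
#'   highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.confluence_scores <- function(object, ...) {
  df <- dplyr::arrange(object$scores, .data$omega_phi)
  df$method <- factor(df$method, levels = df$method)
  df$super <- df$method == object$superdelegate
  ggplot2::ggplot(df, ggplot2::aes(.data$omega_phi, .data$method,
                                   fill = .data$super)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick3")) +
    ggplot2::labs(x = expression(Omega(alpha, phi)), y = NULL,
                  title = paste0("Correlation to the average standardized variable",
                                 " (superdelegate: ", object$superdelegate,
                                 ")")) +
    ggplot2::theme_minimal()
}
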