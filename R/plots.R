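# ggplot2 displays for kernels, envirotype profiles and fits.

#' Heatmap of a similarity kernel
#'
#' @param K Labeled square kernel matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_kernel <- function(K, title = NULL) {
  df <- tibble::as_tibble(as.data.frame(as.table(as.matrix(K))),
                          .name_repair = "minimal")
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "similarity") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Envirotype frequency panel
#'
#' Stacked relative frequencies of each envirotype bin per environment,
#' faceted by variable (and window).
#'
#' @param object An `envirotype_profile` from [env_typing()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envirotype_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$env_id, .data$freq,
                                            fill = .data$bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "environment", y = "frequency of occurrence",
                  fill = "envirotype") +
    ggplot2::theme_minimal()
  if ("window" %in% names(object)) {
    p + ggplot2::facet_grid(window ~ var)
  } else {
    p + ggplot2::facet_wrap(~var)
  }
}

#' Observed versus predicted phenotypes for a kernel model fit
#'
#' @param object A `kernel_fit`.
#' @param ... Unused.
#' @return A ggplot object; prediction targets (missing observations at
#'   fit time) are shown in a separate colour when present.
#' @export
autoplot.kernel_fit <- function(object, ...) {
  df <- augment.kernel_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$.fitted, .data$value,
                                   colour = .data$.predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "predicted", y = "observed",
                  colour = "prediction target") +
    ggplot2::theme_minimal()
}

#' Posterior variance components with credible intervals
#'
#' @param fit A `kernel_fit`.
#' @return A ggplot object.
#' @export
plot_varcomp <- function(fit) {
  vc <- tidy.kernel_fit(fit)
  vc$term <- factor(vc$term, levels = rev(vc$term))
  ggplot2::ggplot(vc, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "posterior variance component", y = NULL) +
    ggplot2::theme_minimal()
}
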