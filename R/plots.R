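# ggplot2 visualisations of the main result types

#' Box plots of trait distributions across environments
#'
#' Fig-style overview of plot-level trait values per environment, faceted by
#' location.
#'
#' @inheritParams genotype_env_means
#' @return A ggplot object.
#' @export
plot_trait_distributions <- function(data, trait) {
  dd <- distribution_data(data, trait)
  ggplot2::ggplot(dd, ggplot2::aes(
    x = factor(.data$environment, levels = env_levels()),
    y = .data$value, fill = .data$environment
  )) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = NULL, y = trait) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.met_cor <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::mutate(td, label = sprintf("%.2f%s", .data$r, .data$stars))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$trait1, y = .data$trait2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(title = sprintf("Trait correlations (%s)", object$environment),
                  x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.index_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"tolerant" %in% names(df)) df$tolerant <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$yp, y = .data$ys,
                                   colour = .data$sti)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$tolerant), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      title = sprintf("%s vs %s yield (%s)", "Optimum",
                      attr(object, "stress_env"), attr(object, "location")),
      x = "Yp (g/plot)", y = "Ys (g/plot)", colour = "STI",
      shape = "Selected"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.met_reduction <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$trait <- factor(df$trait, levels = trait_codes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$mean)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.3) +
    ggplot2::labs(
      title = sprintf("Percent reduction %s at %s",
                      object$contrast[1], attr(object, "location")),
      x = NULL, y = "Reduction (%)"
    ) +
    ggplot2::theme_minimal()
}
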