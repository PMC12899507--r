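#' Heatmap of module-trait correlations
#'
#' @param module_trait tibble from [module_trait_correlation()].
#' @return a ggplot object.
#' @export
plot_module_trait <- function(module_trait) {
  check_columns(module_trait, c("module", "trait", "r"), "module-trait table")
  ggplot2::ggplot(module_trait, ggplot2::aes(x = .data$trait,
                                             y = .data$module,
                                             fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(title = "Module-trait correlation", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Trait time-course panel
#'
#' Mean +/- SD per treatment over stress duration, one facet per trait.
#'
#' @param summary tibble from [summarize_traits()].
#' @param variety optional single variety to show (default: all, colour by
#'   variety).
#' @return a ggplot object.
#' @export
plot_trait_course <- function(summary, variety = NULL) {
  check_columns(summary, c("variety", "treatment", "timepoint_d", "trait",
                           "mean"), "trait summary")
  if (!is.null(variety)) {
    summary <- dplyr::filter(summary, .data$variety %in% !!variety)
  }
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$timepoint_d,
                                        y = .data$mean,
                                        colour = .data$variety,
                                        linetype = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "days of stress", y = "trait value") +
    ggplot2::theme_minimal()
}

#' Germination relative-index profile per tolerance group
#'
#' @param grouping a `tolerance_grouping`.
#' @param rel the relative-index table it was fitted on.
#' @return a ggplot object.
#' @export
plot_tolerance_groups <- function(grouping, rel) {
  df <- dplyr::left_join(rel, tidy(grouping), by = "variety") |>
    tidyr::pivot_longer(dplyr::starts_with("rel_"),
                        names_to = "index", values_to = "relative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$relative,
                                   colour = .data$group,
                                   group = .data$variety)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Relative germination indices by tolerance group",
                  x = NULL, y = "stress / control") +
    ggplot2::theme_minimal()
}
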