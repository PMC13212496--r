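#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs scale_y_continuous geom_tile scale_fill_viridis_c
NULL

#' Plot a simulated assay trajectory
#'
#' @param object A `cart_sim` from [simulate_assay()].
#' @param ... Unused.
#' @return A ggplot: cell counts of the three compartments over time.
#' @export
autoplot.cart_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("T", "CART", "TC"),
                              names_to = "compartment",
                              values_to = "cells")
  ggplot(long, aes(x = .data$time_h, y = .data$cells,
                   color = .data$compartment)) +
    geom_line() +
    labs(x = "time (h)", y = "cells",
         title = sprintf("Simulated assay, E:T = %s",
                         format(attr(object, "et_ratio")))) +
    ggplot2::theme_minimal()
}

#' Plot impedance traces
#'
#' @param traces Tidy trace tibble.
#' @return A ggplot of CI over time, one panel per condition/ratio,
#'   colored by replicate.
#' @export
plot_traces <- function(traces) {
  validate_traces(traces)
  d <- dplyr::mutate(traces, panel = dplyr::if_else(
    .data$condition == "coculture",
    paste0("coculture ", format_ratio(.data$et_ratio)),
    .data$condition))
  ggplot(d, aes(x = .data$time_h, y = .data$ci,
                group = interaction(.data$product_id, .data$replicate),
                color = factor(.data$replicate))) +
    geom_line(alpha = 0.8) +
    facet_wrap(~panel) +
    labs(x = "time (h)", y = "cell index (CI)", color = "replicate") +
    ggplot2::theme_minimal()
}

#' Heatmap of the global sensitivity surface
#'
#' @param surface Output of [global_sensitivity()].
#' @return A ggplot tile map of percent cytolysis over parameter value
#'   and E:T ratio.
#' @export
plot_global_sensitivity <- function(surface) {
  ggplot(surface, aes(x = factor(signif(.data$value, 3)),
                      y = factor(.data$et_ratio),
                      fill = .data$pct_cytolysis)) +
    geom_tile() +
    facet_wrap(~parameter, scales = "free_x") +
    scale_fill_viridis_c(name = "% cytolysis", limits = c(0, 100)) +
    labs(x = "parameter value", y = "E:T ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an E:T ratio sweep
#'
#' @param object A `cart_et_sweep` from [et_sweep()].
#' @param ... Unused.
#' @return A ggplot of percent cytolysis against the (log-scaled) E:T
#'   ratio, with the saturation ratio marked when available.
#' @export
autoplot.cart_et_sweep <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$et_ratio, y = .data$pct_cytolysis)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_log10() +
    scale_y_continuous(limits = c(0, 100)) +
    labs(x = "E:T ratio", y = "% cytolysis") +
    ggplot2::theme_minimal()
  sat <- attr(object, "saturation_ratio")
  if (!is.na(sat)) {
    p <- p + ggplot2::geom_vline(xintercept = sat, linetype = "dashed")
  }
  p
}

#' Parameter distributions across outcome groups
#'
#' @param params_table Parameter tibble with `product_id`.
#' @param groups Output of [assign_groups()].
#' @param parameters Parameters to show.
#' @return A ggplot of boxplots by group, one panel per parameter on a
#'   log scale.
#' @export
plot_cohort_comparison <- function(params_table, groups,
                                   parameters = c("kc", "Kmr", "n", "kp2",
                                                  "Kmp", "CE")) {
  d <- dplyr::inner_join(params_table, groups, by = "product_id") |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "estimate")
  ggplot(d, aes(x = .data$group, y = .data$estimate,
                fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 16) +
    facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_y_log10() +
    labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
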