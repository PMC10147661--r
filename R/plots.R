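# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

node_colors <- c(A = "#E69F00", B = "#0072B2", C = "#009E73",
                 mKO2 = "#E69F00", mKate2 = "#0072B2", sfGFP = "#009E73")

#' Plot a dose response
#'
#' Normalized reporter readouts across the arabinose gradient, the view in
#' which a stripe (low-high-low) phenotype is read.
#'
#' @param object A `grn_dose_response`.
#' @param normalize Normalize each reporter to its maximum first.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grn_dose_response <- function(object, normalize = TRUE, ...) {
  df <- if (normalize) normalize_dose_response(object) else object
  df$ara_plot <- ifelse(df$ara == 0, min(df$ara[df$ara > 0]) / 10, df$ara)
  ggplot2::ggplot(df, ggplot2::aes(.data$ara_plot, .data$value, colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = node_colors) +
    ggplot2::labs(x = "arabinose (% w/v, log scale; leftmost point is 0)",
                  y = if (normalize) "normalized fluorescence" else "fluorescence (a.u.)",
                  colour = "node",
                  title = unique(df$genotype)[1]) +
    ggplot2::theme_minimal()
}

#' Plot reporter trajectories
#'
#' @param object A `grn_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the three mature reporters over time.
#' @export
autoplot.grn_trajectory <- function(object, ...) {
  model <- attr(object, "model")
  df <- tibble::as_tibble(as.data.frame(unclass(object)))
  df <- tidyr::pivot_longer(df[, c("time", paste0("P.", c("A", "B", "C")))],
                            -"time", names_to = "node", values_to = "value")
  df$node <- sub("^P\\.", "", df$node)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = node_colors) +
    ggplot2::labs(x = "time (min)", y = "mature reporter (nM)",
                  title = encode_genotype(model$genotype, model$parts)) +
    ggplot2::theme_minimal()
}

#' Plot a phenotype transition matrix
#'
#' @param object A `grn_transitions` from [transition_frequencies()].
#' @param ... Unused.
#' @return A ggplot tile matrix of median transition frequencies with IQR
#'   annotations.
#' @export
autoplot.grn_transitions <- function(object, ...) {
  df <- object
  df$lab <- sprintf("%.2f\n(%.2f-%.2f)", df$median, df$q25, df$q75)
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source, fill = .data$median)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#444444", limits = c(0, 1)) +
    ggplot2::labs(x = "target phenotype", y = "source phenotype",
                  fill = "median\nfrequency") +
    ggplot2::theme_minimal()
}

#' Plot the topology evolvability plane
#'
#' Mean evolvability over the full neighborhood versus over fixed-topology
#' neighbors, one circle per topology, sized by edge count and coloured by
#' k-means cluster.
#'
#' @param object A `grn_topology_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grn_topology_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$E, .data$E_F,
                                       size = .data$n_edges,
                                       colour = factor(.data$cluster))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "evolvability (all neighbors)",
                  y = "evolvability (fixed topology)",
                  size = "repressions", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-slot robustness distributions
#'
#' @param object Output of [robustness_per_perturbation()].
#' @param ... Unused.
#' @return A ggplot violin/box per perturbation slot (1-6 sgRNA slots,
#'   7-8 promoter slots).
#' @export
plot_perturbation_robustness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$slot), .data$robustness)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.3) +
    ggplot2::labs(x = "perturbation slot (1-6: edges, 7-8: promoters)",
                  y = "robustness per perturbation") +
    ggplot2::theme_minimal()
}
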