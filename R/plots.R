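#' Alpha-diversity box plots by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param groups Named sample -> group vector.
#' @return A ggplot: one panel per metric, boxes per group with sample points.
#' @export
plot_alpha <- function(alpha, groups) {
  df <- dplyr::mutate(alpha, group = unname(groups[.data$sample_id]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median_value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median over rarefactions") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Ordination scatter (first two axes)
#'
#' @param ordination Result of [pcoa_ordination()].
#' @param groups Named sample -> group vector.
#' @param axes Which two axes to draw (default 1:2).
#' @return A ggplot of the samples in ordination space, colored by group,
#'   axes annotated with their explained share.
#' @export
plot_ordination <- function(ordination, groups, axes = c(1, 2)) {
  wide <- tidyr::pivot_wider(ordination$coordinates,
                             names_from = "axis", values_from = "value",
                             names_prefix = "axis_")
  rel <- ordination$relative_eig
  lab <- function(a) sprintf("PCo%d (%.1f%%)", a, 100 * rel[a])
  ggplot2::ggplot(wide, ggplot2::aes(
    x = .data[[paste0("axis_", axes[1])]],
    y = .data[[paste0("axis_", axes[2])]],
    color = unname(groups[wide$sample_id]))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2]), color = "group") +
    ggplot2::theme_bw()
}

#' Volcano plot of a differential-abundance result
#'
#' @param object A `phg_diff` from [nb_differential()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change vs -log10 adjusted p, flagged contigs
#'   highlighted, thresholds drawn.
#' @export
autoplot.phg_diff <- function(object, ...) {
  params <- attr(object, "params")
  df <- tidy(object)
  df <- df[!is.na(df$bh_adjusted_p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(.data$bh_adjusted_p),
                                   color = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = params$lfc_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(params$alpha), linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 BH-adjusted p",
                  color = "over-abundant") +
    ggplot2::theme_bw()
}

#' Prevalence-class bar chart
#'
#' @param classes Tibble from [classify_prevalence()].
#' @return A ggplot of contig counts per prevalence class.
#' @export
plot_prevalence_classes <- function(classes) {
  df <- dplyr::count(classes, .data$class)
  df$class <- factor(df$class, levels = c("core", "common", "individual"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = "prevalence class", y = "contigs") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
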