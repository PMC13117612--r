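#' Volcano plot of a marker table
#'
#' Delta percentage (difference in the fraction of expressing cells)
#' against log2 fold change, with specific genes highlighted — the
#' standard single-cell specificity volcano.
#'
#' @param object A [find_markers()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta_pct, y = .data$log2fc,
                               colour = .data$specific)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(Delta ~ "percentage (pct.1 - pct.2)"),
      y = expression(log[2] ~ "(fold change)"),
      colour = "specific",
      title = unique(paste(object$group1, "vs", object$group2))
    ) +
    ggplot2::theme_minimal()
}

#' Pair-correlation distribution by configuration
#'
#' @param object A [correlate_pairs()] table.
#' @param ... Unused.
#' @return A ggplot object (boxplots of r per configuration).
#' @export
autoplot.pair_cor_table <- function(object, ...) {
  df <- dplyr::filter(object, .data$defined, .data$cell_group == "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$configuration, y = .data$r,
                                   fill = .data$configuration)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genomic configuration",
                  y = "Pearson r (lncRNA vs PCG)") +
    ggplot2::theme_minimal()
}

#' Configuration frequency bar chart
#'
#' @param freqs A [configuration_frequencies()] table.
#' @return A ggplot object.
#' @export
plot_configuration_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs,
                  ggplot2::aes(x = .data$configuration,
                               y = 100 * .data$fraction,
                               fill = .data$configuration)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "configuration", y = "% of proximal pairs") +
    ggplot2::theme_minimal()
}

#' Group velocity-length summary plot
#'
#' Mean velocity length against mean transcript abundance per group:
#' terminal, transcriptionally quiescent groups sit in the lower left.
#'
#' @param summary A [group_velocity_summary()] table.
#' @return A ggplot object.
#' @export
plot_velocity_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$mean_total,
                               y = .data$mean_velocity_length,
                               label = .data$group)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "mean total transcripts",
                  y = "mean velocity length") +
    ggplot2::theme_minimal()
}

#' Atlas cluster profile plot
#'
#' Z-scored cluster centre profiles over the cell groups.
#'
#' @param object A [cluster_lnc_profiles()] atlas.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_atlas <- function(object, ...) {
  df <- as.data.frame(object$centers)
  df$cluster <- factor(seq_len(nrow(df)))
  df <- tidyr::pivot_longer(df, -"cluster", names_to = "group",
                            values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$z,
                                   group = .data$cluster,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "cell group", y = "z-scored mean expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
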