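# Convenience figures for the main result tables.

#' Distribution of taxon APE values per treatment
#'
#' Dot/violin view of per-replicate taxon APE \eqn{^{18}}O with the active
#' (0%) and growing (5%) thresholds marked.
#'
#' @param enrichment a [enrich_all()] table.
#' @param growing_threshold APE (%) marking growing taxa.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, growing_threshold = 5) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$treatment, y = .data$ape)) +
    ggplot2::geom_violin(fill = "grey90", colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = c(0, growing_threshold),
                        linetype = c("solid", "dashed"), colour = "firebrick") +
    ggplot2::labs(x = NULL, y = expression("APE" ~ {}^18 * O ~ "(%)")) +
    ggplot2::theme_minimal()
}

#' Per-sample growing-community summaries across treatments
#'
#' @param sample_summary output of [summarize_samples()].
#' @param metric one of `"growing_pct"`, `"growing_richness"`,
#'   `"mean_rgr_growing"`, `"mean_rgr_all"`.
#' @return A ggplot object.
#' @export
plot_sample_summary <- function(sample_summary,
                                metric = c("growing_pct", "growing_richness",
                                           "mean_rgr_growing", "mean_rgr_all")) {
  metric <- match.arg(metric)
  labels <- c(growing_pct = "Growing community (% of 16S copies)",
              growing_richness = "Growing taxa (count)",
              mean_rgr_growing = "Mean RGR, growing taxa (per day)",
              mean_rgr_all = "Mean RGR, all taxa (per day)")
  ggplot2::ggplot(sample_summary,
                  ggplot2::aes(x = .data$treatment, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = labels[[metric]]) +
    ggplot2::theme_minimal()
}
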