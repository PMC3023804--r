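## ggplot2 displays for the result types.

#' Peak category distribution plot
#'
#' Bar chart of the genomic-location categories of a peak set.
#'
#' @param summary Output of [summarize_categories()].
#' @return A ggplot object.
#' @export
plot_category_distribution <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of peaks",
                  title = "Peak location relative to gene models") +
    ggplot2::theme_minimal()
}

#' Knockdown-versus-ligand response scatter
#'
#' log2 fold change under receptor knockdown against log2 fold change under
#' agonist treatment, coloured by response class, with the classification
#' thresholds drawn.
#'
#' @param targets A `chiptarget_targets` tibble (or [tidy()] of a run).
#' @param cfg A [pipeline_config()] supplying the threshold lines.
#' @return A ggplot object.
#' @export
plot_response_scatter <- function(targets, cfg = pipeline_config()) {
  ggplot2::ggplot(targets,
                  ggplot2::aes(x = log2(.data$fc_ligand),
                               y = log2(.data$fc_sirna),
                               colour = .data$response)) +
    ggplot2::geom_hline(yintercept = c(1, -1) * log2(cfg$fc_sirna_min),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = log2(cfg$fc_ligand_min),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      type_I = "#d62728", type_II = "#1f77b4", type_III = "#2ca02c",
      ligand_only = "#9467bd", unclassified = "grey50")) +
    ggplot2::labs(x = "log2 FC (agonist vs solvent)",
                  y = "log2 FC (receptor siRNA vs control)",
                  colour = "response") +
    ggplot2::theme_minimal()
}

#' @describeIn run_target_pipeline Autoplot: `type = "categories"` (all
#'   peaks), `"categories_targets"`, or `"responses"`.
#' @param object A `chiptarget_run`.
#' @param type Which display to draw.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.chiptarget_run <- function(object,
                                    type = c("categories",
                                             "categories_targets",
                                             "responses"), ...) {
  type <- match.arg(type)
  switch(type,
         categories = plot_category_distribution(object$category_summary_all),
         categories_targets =
           plot_category_distribution(object$category_summary_targets),
         responses = plot_response_scatter(object$targets, object$config))
}

#' Autoplot an enrichment result
#'
#' Enrichment ratio against statistical significance per trait.
#'
#' @param object A `chiptarget_enrichment` tibble.
#' @param q_cutoff Significance line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.chiptarget_enrichment <- function(object, q_cutoff = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$enrichment,
                               y = -log10(.data$q_value))) +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$trait), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = "enrichment (observed / null mean)",
                  y = "-log10 q-value") +
    ggplot2::theme_minimal()
}
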