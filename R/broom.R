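## tidy()/glance() methods for the two fitted-result types.

#' Tidy a pipeline run
#'
#' One row per target gene with its response label, fold changes and
#' supporting-peak count.
#'
#' @param x A `chiptarget_run`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.chiptarget_run <- function(x, ...) {
  as_tibble(x$targets) %>%
    select("gene_id", "response", "fc_sirna", "fc_ligand", "n_peaks",
           "probe_id")
}

#' One-row summary of a pipeline run
#'
#' The cascade counts: total, high-confidence, H3K4me3-partnered and
#' Pol-II-positive peaks, expression-correlated peaks and target genes.
#'
#' @param x A `chiptarget_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.chiptarget_run <- function(x, ...) {
  as_tibble(x$report)
}

#' Tidy an enrichment result
#'
#' @param x A `chiptarget_enrichment` tibble.
#' @param ... Unused.
#' @return The underlying tibble (one row per trait).
#' @exportS3Method generics::tidy
tidy.chiptarget_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an enrichment result
#'
#' @param x A `chiptarget_enrichment` tibble.
#' @param ... Unused.
#' @return Tibble with the number of traits, trials, and significant traits
#'   at q <= 0.05.
#' @exportS3Method generics::glance
glance.chiptarget_enrichment <- function(x, ...) {
  tibble(n_traits = nrow(x), n_trials = x$n_trials[1],
         n_significant = sum(x$q_value <= 0.05),
         min_q = min(x$q_value))
}
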