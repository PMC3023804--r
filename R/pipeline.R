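## End-to-end orchestration of the target-gene definition cascade:
## peaks -> high-confidence -> H3K4me3-partnered (Pol II annotated) ->
## gene links -> probe assignment -> regulated representative probes ->
## target genes with response labels.

#' Run the target-gene definition cascade
#'
#' Executes every stage on in-memory tables and collects the per-stage
#' counts, annotated peaks and the target-gene set.
#'
#' @param peaks ChIP peak tibble for the factor of interest.
#' @param h3k4 H3K4me3 peak tibble.
#' @param polII_tags Pol II tag-track tibble (`chrom`, `pos`).
#' @param genes Gene-model tibble.
#' @param alignments Probe alignment records.
#' @param expression Expression tibble.
#' @param cfg A [pipeline_config()].
#' @param all_probe_ids Optional complete probe universe (see
#'   [assign_probes()]).
#' @return Object of class `chiptarget_run`: a list with `report`
#'   (stage counts), `peaks_all` (categorised input peaks),
#'   `peaks_annotated` (high-confidence peaks with H3K4me3/Pol II
#'   annotation), `links`, `assignments`, `targets`
#'   (a `chiptarget_targets` tibble), `category_summary_all`,
#'   `category_summary_targets`, `venn`, `response_counts`, `config`.
#' @export
run_target_pipeline <- function(peaks, h3k4, polII_tags, genes, alignments,
                                expression, cfg = pipeline_config(),
                                all_probe_ids = NULL) {
  cat_all <- categorize_peaks(peaks, genes, cfg)
  hc <- filter_high_confidence(peaks, cfg)
  assoc <- associate_h3k4me3(hc, h3k4, cfg)
  if (!"peak_id" %in% names(h3k4)) {
    h3k4$peak_id <- sprintf("h3k4_%05d", seq_len(nrow(h3k4)))
  }
  partner_iv <- h3k4[match(assoc$h3k4_partner, h3k4$peak_id), ]
  assoc$polII_positive <- FALSE
  has_partner <- !is.na(assoc$h3k4_partner)
  if (any(has_partner)) {
    assoc$polII_positive[has_partner] <-
      polII_occupancy(partner_iv[has_partner, c("chrom", "start", "end")],
                      polII_tags, cfg)
  }
  partnered <- assoc %>% filter(.data$h3k4_partnered)
  links <- link_peaks_to_genes(partnered, genes, cfg)
  assignments <- assign_probes(alignments, genes, cfg, all_probe_ids)
  targets <- build_target_set(assoc, links, assignments, expression, cfg)
  cat_targets <- cat_all %>%
    filter(.data$peak_id %in% unlist(targets$peak_ids))
  venn <- overlap_summary(tibble(
    sirna_regulated = targets$fc_sirna >= cfg$fc_sirna_min |
      targets$fc_sirna <= 1 / cfg$fc_sirna_min,
    ligand_regulated = targets$fc_ligand >= cfg$fc_ligand_min))
  response_counts <- targets %>%
    count(.data$response, .drop = FALSE, name = "n")
  report <- list(
    n_peaks_total = nrow(peaks),
    n_high_confidence = nrow(hc),
    n_h3k4_partnered = nrow(partnered),
    n_polII_positive = sum(partnered$polII_positive),
    n_expression_correlated_peaks = attr(targets, "n_supporting_peaks"),
    n_target_genes = nrow(targets),
    n_linked_genes_no_probe = attr(targets, "n_genes_no_probe"),
    pct_h3k4_partnered = if (nrow(hc) > 0) 100 * nrow(partnered) / nrow(hc)
                         else NA_real_,
    pct_polII_positive = if (nrow(partnered) > 0) {
      100 * sum(partnered$polII_positive) / nrow(partnered)
    } else NA_real_
  )
  structure(list(report = report, peaks_all = cat_all,
                 peaks_annotated = assoc, links = links,
                 assignments = assignments, targets = targets,
                 category_summary_all = summarize_categories(cat_all),
                 category_summary_targets = summarize_categories(cat_targets),
                 venn = venn, response_counts = response_counts,
                 config = cfg),
            class = "chiptarget_run")
}

#' @export
print.chiptarget_run <- function(x, ...) {
  r <- x$report
  cat("<chiptarget_run>\n")
  cat(sprintf("  peaks: %d total -> %d high-confidence -> %d H3K4me3-partnered (%.1f%%)\n",
              r$n_peaks_total, r$n_high_confidence, r$n_h3k4_partnered,
              r$pct_h3k4_partnered))
  cat(sprintf("  Pol II positive partnered peaks: %d (%.1f%%)\n",
              r$n_polII_positive, r$pct_polII_positive))
  cat(sprintf("  expression-correlated peaks: %d -> target genes: %d\n",
              r$n_expression_correlated_peaks, r$n_target_genes))
  resp <- x$response_counts
  cat("  responses:", paste(sprintf("%s=%d", resp$response, resp$n),
                            collapse = " "), "\n")
  invisible(x)
}

#' Run the cascade from a configuration file
#'
#' File-based front end for [run_target_pipeline()]: reads every input
#' named in a YAML (or list) configuration, runs the cascade, and writes
#' the annotated peaks, the target-gene table, and a machine-readable JSON
#' report into the output directory. Re-running with an identical
#' configuration produces byte-identical outputs.
#'
#' Configuration fields: `peaks`, `h3k4_peaks`, `polII_bed`, `genes`,
#' `gene_format` (`gff3`/`bed12`/`tsv`), `alignments`, `expression`,
#' `out_dir`, and optionally any [pipeline_config()] threshold under
#' `thresholds:`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The `chiptarget_run` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("peaks", "h3k4_peaks", "polII_bed", "genes", "alignments",
            "expression", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    abort(sprintf("pipeline config is missing field(s): %s",
                  paste(miss, collapse = ", ")))
  }
  for (f in setdiff(need, "out_dir")) {
    if (!file.exists(config[[f]])) {
      abort(sprintf("input `%s` does not exist: %s", f, config[[f]]))
    }
  }
  cfg <- do.call(pipeline_config, config$thresholds %||% list())
  run <- run_target_pipeline(
    peaks = read_peak_table(config$peaks),
    h3k4 = read_peak_table(config$h3k4_peaks),
    polII_tags = read_tag_track(config$polII_bed, label = "PolII"),
    genes = read_gene_models(config$genes,
                             format = config$gene_format %||% "tsv"),
    alignments = read_probe_alignments(config$alignments),
    expression = read_expression_table(config$expression),
    cfg = cfg)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$peaks_annotated %>%
                     select(-dplyr::any_of(c("tx_starts", "tx_ends"))),
                   file.path(config$out_dir, "annotated_peaks.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$targets %>%
                     mutate(peak_ids = vapply(.data$peak_ids, paste,
                                              character(1), collapse = ";")),
                   file.path(config$out_dir, "target_genes.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(report = run$report,
         response_counts = run$response_counts,
         venn = run$venn,
         config = unclass(cfg)),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run)
}

#' @importFrom rlang %||%
NULL
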