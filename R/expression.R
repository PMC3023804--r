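## Regulation calls from the dual-perturbation expression table, response
## classification (type I / II / III), the target-gene join and the
## knockdown-vs-ligand overlap summary.

#' Call regulated probes
#'
#' A probe passes the intensity gate when `avg_log_intensity >=
#' intensity_min` (inclusive). Among passing probes, the knockdown response
#' is `up` at `fc_sirna >= fc_sirna_min`, `down` at `fc_sirna <=
#' 1/fc_sirna_min`, otherwise `none`; the ligand response uses
#' `fc_ligand_min` analogously. Probes failing the gate are `none` in both
#' conditions.
#'
#' @param expr Expression tibble (`probe_id`, `avg_log_intensity`,
#'   `fc_sirna`, `fc_ligand`; linear fold changes > 0).
#' @param cfg A [pipeline_config()].
#' @return `expr` with `passes_intensity`, `sirna_regulated`,
#'   `ligand_regulated` appended.
#' @export
call_regulated <- function(expr, cfg = pipeline_config()) {
  expr <- as_tibble(expr)
  if (nrow(expr) > 0 && any(expr$fc_sirna <= 0 | expr$fc_ligand <= 0)) {
    abort("fold changes must be > 0")
  }
  dir_call <- function(fc, thr, gate) {
    out <- rep("none", length(fc))
    out[gate & fc >= thr] <- "up"
    out[gate & fc <= 1 / thr] <- "down"
    factor(out, levels = c("up", "down", "none"))
  }
  gate <- expr$avg_log_intensity >= cfg$intensity_min
  expr %>%
    mutate(passes_intensity = gate,
           sirna_regulated = dir_call(.data$fc_sirna, cfg$fc_sirna_min, gate),
           ligand_regulated = dir_call(.data$fc_ligand, cfg$fc_ligand_min, gate))
}

#' Classify the transcriptional response mode
#'
#' Partitions the positive fold-change quadrant into five mutually
#' exclusive labels:
#' * `type_I` — up-regulated by knockdown (`fc_sirna >= fc_sirna_min`),
#'   not induced by ligand (`fc_ligand < fc_ligand_min`): ligand-independent
#'   repression by the receptor;
#' * `type_II` — up-regulated by knockdown and induced by ligand
#'   (`fc_ligand >= fc_ligand_min`): repression released by ligand;
#' * `type_III` — down-regulated by knockdown (`fc_sirna <=
#'   1/fc_sirna_min`), ligand response unconstrained (optionally capped via
#'   `type3_ligand_cap`): ligand-independent activation;
#' * `ligand_only` — induced by ligand without a knockdown response;
#' * `unclassified` — everything else.
#'
#' @param fc_sirna,fc_ligand Positive linear fold changes (vectorised).
#' @param cfg A [pipeline_config()].
#' @return Factor with levels `type_I`, `type_II`, `type_III`,
#'   `ligand_only`, `unclassified`.
#' @export
classify_response <- function(fc_sirna, fc_ligand, cfg = pipeline_config()) {
  if (any(fc_sirna <= 0 | fc_ligand <= 0, na.rm = TRUE)) {
    abort("fold changes must be > 0")
  }
  up <- fc_sirna >= cfg$fc_sirna_min
  down <- fc_sirna <= 1 / cfg$fc_sirna_min
  lig <- fc_ligand >= cfg$fc_ligand_min
  out <- rep("unclassified", length(fc_sirna))
  out[up & !lig] <- "type_I"
  out[up & lig] <- "type_II"
  type3 <- down
  if (!is.null(cfg$type3_ligand_cap)) type3 <- down & fc_ligand <= cfg$type3_ligand_cap
  out[type3] <- "type_III"
  out[lig & !up & !down] <- "ligand_only"
  factor(out, levels = c("type_I", "type_II", "type_III", "ligand_only",
                         "unclassified"))
}

#' Knockdown / ligand regulation overlap at gene level
#'
#' Partition of regulated genes into knockdown-only, ligand-only and both
#' (the Venn counts of the target-definition analysis).
#'
#' @param gene_calls Tibble with one row per gene and logical columns
#'   `sirna_regulated`, `ligand_regulated` (or the factors produced by
#'   [call_regulated()], where any non-`none` level counts as regulated).
#' @return Tibble with columns `sirna_only`, `ligand_only`, `both`,
#'   `total` (`total = sirna_only + ligand_only + both`).
#' @export
overlap_summary <- function(gene_calls) {
  as_reg <- function(x) if (is.logical(x)) x else x != "none"
  if (nrow(gene_calls) == 0) {
    return(tibble(sirna_only = 0L, ligand_only = 0L, both = 0L, total = 0L))
  }
  s <- as_reg(gene_calls$sirna_regulated)
  l <- as_reg(gene_calls$ligand_regulated)
  tibble(sirna_only = sum(s & !l), ligand_only = sum(l & !s),
         both = sum(s & l), total = sum(s | l))
}

#' Build the target-gene set
#'
#' A gene enters the target set when (a) it is linked (within the gene-link
#' window) to at least one high-confidence, H3K4me3-partnered peak and (b)
#' its representative probe is regulated by knockdown and/or ligand. Each
#' target gene carries its supporting peaks, representative probe, fold
#' changes and response label.
#'
#' @param annotated_peaks High-confidence peaks annotated by
#'   [associate_h3k4me3()] (column `h3k4_partnered`).
#' @param links Peak-gene link table from [link_peaks_to_genes()].
#' @param assignments Probe assignments from [assign_probes()].
#' @param expr Expression tibble.
#' @param cfg A [pipeline_config()].
#' @return Tibble of class `chiptarget_targets`: `gene_id`, `peak_ids`
#'   (list), `n_peaks`, `probe_id`, `fc_sirna`, `fc_ligand`, `response`.
#'   Attributes `n_supporting_peaks` (distinct expression-correlated peaks)
#'   and `n_genes_no_probe` (linked genes skipped for lack of an
#'   intensity-passing probe) summarise the join.
#' @export
build_target_set <- function(annotated_peaks, links, assignments, expr,
                             cfg = pipeline_config()) {
  good_peaks <- annotated_peaks %>% filter(.data$h3k4_partnered)
  links <- links %>% filter(.data$peak_id %in% good_peaks$peak_id)
  gene2probe <- assignments %>%
    select("probe_id", "gene_ids") %>%
    tidyr::unnest(cols = "gene_ids") %>%
    rename(gene_id = "gene_ids")
  calls <- call_regulated(expr, cfg)
  empty <- tibble(gene_id = character(), peak_ids = list(),
                  n_peaks = integer(), probe_id = character(),
                  fc_sirna = numeric(), fc_ligand = numeric(),
                  response = factor(character(),
                                    levels = levels(classify_response(1, 1, cfg))))
  linked_genes <- unique(links$gene_id)
  n_no_probe <- 0L
  rows <- purrr::map(linked_genes, function(g) {
    probes <- gene2probe$probe_id[gene2probe$gene_id == g]
    e <- calls %>% filter(.data$probe_id %in% probes)
    if (nrow(e) == 0) return(NULL)
    rep_probe <- select_representative_probe(e, cfg)
    if (is.na(rep_probe)) return(NULL)
    er <- e %>% filter(.data$probe_id == rep_probe)
    regulated <- er$sirna_regulated != "none" | er$ligand_regulated != "none"
    if (!regulated) return(NA)  # had a probe, just not regulated
    pk <- sort(unique(links$peak_id[links$gene_id == g]))
    tibble(gene_id = g, peak_ids = list(pk), n_peaks = length(pk),
           probe_id = rep_probe, fc_sirna = er$fc_sirna,
           fc_ligand = er$fc_ligand,
           response = classify_response(er$fc_sirna, er$fc_ligand, cfg))
  })
  n_no_probe <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, function(x) is.null(x) || !is.data.frame(x),
                       logical(1))]
  out <- if (length(rows) > 0) bind_rows(rows) %>% arrange(.data$gene_id) else empty
  attr(out, "n_supporting_peaks") <- length(unique(unlist(out$peak_ids)))
  attr(out, "n_genes_no_probe") <- n_no_probe
  class(out) <- c("chiptarget_targets", class(out))
  out
}
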