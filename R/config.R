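#' Pipeline configuration
#'
#' Collects every tunable threshold of the target-gene definition cascade.
#' Defaults reproduce the published analysis settings.
#'
#' Boundary conventions (tested exhaustively): `fdr_max` and
#' `control_tags_max` are strict upper bounds ("less than 5%", "fewer than
#' 100 tags"); `polII_min_tags` is a strict lower bound ("more than 50
#' tags"); the distance windows (`h3k4_window`, `upstream_max`,
#' `gene_link_window`) and the expression thresholds (`intensity_min`,
#' `fc_sirna_min`, `fc_ligand_min`) are inclusive.
#'
#' @param fdr_max Peak FDR strict upper bound.
#' @param control_tags_max Strict upper bound on control (IgG) tags in a peak.
#' @param h3k4_window Maximum edge-to-edge distance (bp, inclusive) between a
#'   peak and its nearest H3K4me3 peak.
#' @param polII_min_tags Pol II tag count a region must strictly exceed.
#' @param tss_flank_upstream Upstream extent (bp) of the TSS-flanking window.
#' @param upstream_max Maximum upstream distance (bp, inclusive) for the
#'   `upstream` peak category.
#' @param gene_link_window Maximum peak-to-gene distance (bp, inclusive) for
#'   peak-gene links.
#' @param exclude_peak_ids Peak ids removed manually (e.g. after visual
#'   inspection); modelled as an explicit list, never inferred.
#' @param intensity_min Inclusive probe intensity gate (averaged log scale).
#' @param fc_sirna_min Inclusive knockdown fold-change threshold
#'   (down-regulation at `<= 1/fc_sirna_min`).
#' @param fc_ligand_min Inclusive ligand fold-change threshold.
#' @param type3_ligand_cap Optional upper cap on the ligand fold change for
#'   the type III call; `NULL` (default) leaves ligand response unconstrained.
#' @param probe_3prime_window Distance (bp, inclusive) defining "within 2 kb"
#'   in the probe-assignment cascade.
#' @param h3k4_merge_gap Optional gap (bp) for pre-merging H3K4me3 peaks into
#'   clusters before association; `NULL` (default) treats each peak singly.
#' @return An object of class `chiptarget_config` (a named list).
#' @export
pipeline_config <- function(fdr_max = 0.05,
                            control_tags_max = 100,
                            h3k4_window = 200000,
                            polII_min_tags = 50,
                            tss_flank_upstream = 5000,
                            upstream_max = 25000,
                            gene_link_window = 200000,
                            exclude_peak_ids = character(),
                            intensity_min = 6,
                            fc_sirna_min = 1.5,
                            fc_ligand_min = 1.2,
                            type3_ligand_cap = NULL,
                            probe_3prime_window = 2000,
                            h3k4_merge_gap = NULL) {
  stopifnot(fdr_max > 0, fdr_max <= 1, control_tags_max > 0,
            h3k4_window > 0, upstream_max > 0, gene_link_window > 0,
            tss_flank_upstream > 0, fc_sirna_min > 1, fc_ligand_min > 1)
  structure(list(
    fdr_max = fdr_max, control_tags_max = control_tags_max,
    h3k4_window = h3k4_window, polII_min_tags = polII_min_tags,
    tss_flank_upstream = tss_flank_upstream, upstream_max = upstream_max,
    gene_link_window = gene_link_window, exclude_peak_ids = exclude_peak_ids,
    intensity_min = intensity_min, fc_sirna_min = fc_sirna_min,
    fc_ligand_min = fc_ligand_min, type3_ligand_cap = type3_ligand_cap,
    probe_3prime_window = probe_3prime_window, h3k4_merge_gap = h3k4_merge_gap
  ), class = "chiptarget_config")
}

#' @export
print.chiptarget_config <- function(x, ...) {
  cat("<chiptarget_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
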