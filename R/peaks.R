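## The peak side of the cascade: high-confidence filtering, genomic-location
## categorisation relative to gene models, H3K4me3 association, Pol II
## occupancy and peak-to-gene linking.

#' Filter peaks to the high-confidence set
#'
#' Retains peaks with `fdr < fdr_max` (strict), `control_tags <
#' control_tags_max` (strict) and an id not on the manual exclusion list.
#' Input order is preserved.
#'
#' @param peaks Peak tibble (needs `fdr` and `control_tags`).
#' @param cfg A [pipeline_config()].
#' @return The retained subset of `peaks`.
#' @export
filter_high_confidence <- function(peaks, cfg = pipeline_config()) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) return(peaks)
  if (any(is.na(peaks$fdr))) {
    abort(sprintf("peak(s) without an FDR: %s",
                  paste(head(peaks$peak_id[is.na(peaks$fdr)], 5), collapse = ", ")))
  }
  peaks %>%
    filter(.data$fdr < cfg$fdr_max,
           .data$control_tags < cfg$control_tags_max,
           !.data$peak_id %in% cfg$exclude_peak_ids)
}

# Peak anchor point: summit offset when present, else interval midpoint.
.peak_anchor <- function(peaks) {
  ifelse(!is.na(peaks$summit), peaks$start + peaks$summit,
         floor((peaks$start + peaks$end) / 2))
}

#' Categorise peaks by genomic location
#'
#' Each peak's anchor (summit when present, else midpoint) is placed into one
#' of four categories with precedence `tss_flanking` > `intragenic` >
#' `upstream` > `distant`:
#' * `tss_flanking`: within the strand-aware window from
#'   `tss_flank_upstream` bp upstream of a TSS to the 3' end of the first
#'   intron of the gene's reference transcript;
#' * `intragenic`: inside a gene span;
#' * `upstream`: within `upstream_max` bp (inclusive) upstream of a TSS;
#' * `distant`: none of the above.
#'
#' The anchor gene is the gene with the nearest TSS among genes satisfying
#' the winning category (ties broken by gene id), and
#' `signed_tss_distance` is strand-aware (negative = upstream of the TSS).
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param cfg A [pipeline_config()].
#' @return `peaks` with columns `category` (factor), `anchor_gene_id`,
#'   `signed_tss_distance` appended.
#' @export
categorize_peaks <- function(peaks, genes, cfg = pipeline_config()) {
  peaks <- as_tibble(peaks)
  lvls <- c("tss_flanking", "intragenic", "upstream", "distant")
  if (nrow(peaks) == 0) {
    return(peaks %>% mutate(category = factor(character(), levels = lvls),
                            anchor_gene_id = character(),
                            signed_tss_distance = numeric()))
  }
  p <- .peak_anchor(peaks)
  ann <- tibble(category = factor(rep("distant", nrow(peaks)), levels = lvls),
                anchor_gene_id = NA_character_,
                signed_tss_distance = NA_real_)
  if (nrow(genes) > 0) {
    # candidate peak-gene pairs within the widest relevant window
    reach <- max(cfg$upstream_max, cfg$tss_flank_upstream)
    anchors <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(p + 1, p + 1))
    gspan <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1, genes$end))
    hits <- GenomicRanges::findOverlaps(anchors, gspan, maxgap = reach,
                                        ignore.strand = TRUE)
    if (length(hits) > 0) {
      pi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
      g <- genes[gi, ]
      pos <- p[pi]
      signed <- ifelse(g$strand == "+", pos - g$tss, g$tss - pos)
      in_flank <- ifelse(
        g$strand == "+",
        pos >= g$tss - cfg$tss_flank_upstream & pos < g$first_intron_end,
        pos > g$first_intron_end & pos <= g$tss + cfg$tss_flank_upstream)
      in_gene <- pos >= g$start & pos < g$end
      in_up <- signed < 0 & signed >= -cfg$upstream_max
      pairs <- tibble(pi = pi, gene_id = g$gene_id, signed = signed,
                      in_flank = in_flank, in_gene = in_gene, in_up = in_up)
      best <- pairs %>%
        group_by(.data$pi) %>%
        summarise(
          category = if (any(.data$in_flank)) "tss_flanking"
                     else if (any(.data$in_gene)) "intragenic"
                     else if (any(.data$in_up)) "upstream"
                     else "distant",
          anchor_gene_id = {
            sel <- switch(category[1],
                          tss_flanking = .data$in_flank,
                          intragenic = .data$in_gene,
                          upstream = .data$in_up,
                          rep(FALSE, n()))
            if (any(sel)) {
              o <- order(abs(.data$signed[sel]), .data$gene_id[sel])
              .data$gene_id[sel][o][1]
            } else NA_character_
          },
          signed_tss_distance = {
            sel <- .data$gene_id == anchor_gene_id[1]
            if (any(sel, na.rm = TRUE)) .data$signed[which(sel)[1]] else NA_real_
          },
          .groups = "drop")
      ann$category[best$pi] <- best$category
      ann$anchor_gene_id[best$pi] <- best$anchor_gene_id
      ann$signed_tss_distance[best$pi] <- best$signed_tss_distance
    }
  }
  bind_cols(peaks, ann)
}

#' Summarise peak categories
#'
#' @param categorized Output of [categorize_peaks()].
#' @return Tibble `category`, `n`, `fraction`; counts sum to the input size
#'   and all four categories are always present. An empty input yields zero
#'   counts and zero fractions with a warning.
#' @export
summarize_categories <- function(categorized) {
  lvls <- c("tss_flanking", "intragenic", "upstream", "distant")
  n_tot <- nrow(categorized)
  if (n_tot == 0) {
    warn("no peaks: category fractions reported as 0")
    return(tibble(category = factor(lvls, levels = lvls), n = 0L, fraction = 0))
  }
  tab <- table(factor(categorized$category, levels = lvls))
  tibble(category = factor(lvls, levels = lvls),
         n = as.integer(tab),
         fraction = as.integer(tab) / n_tot)
}

#' Associate peaks with their nearest H3K4me3 peak
#'
#' Finds, for every peak, the nearest H3K4me3 peak (edge-to-edge distance)
#' and flags the peak as partnered when that distance is at most
#' `h3k4_window` (inclusive). Unpartnered peaks are flagged, not dropped;
#' downstream stages filter. With `h3k4_merge_gap` set in the config,
#' H3K4me3 peaks are pre-merged into clusters at that gap.
#'
#' @param peaks Peak tibble.
#' @param h3k4_peaks H3K4me3 peak tibble (a `peak_id` column is generated
#'   when absent).
#' @param cfg A [pipeline_config()].
#' @return `peaks` with `h3k4_partner`, `h3k4_distance`, `h3k4_partnered`
#'   appended.
#' @export
associate_h3k4me3 <- function(peaks, h3k4_peaks, cfg = pipeline_config()) {
  peaks <- as_tibble(peaks)
  h3k4 <- as_tibble(h3k4_peaks)
  if (!is.null(cfg$h3k4_merge_gap)) {
    h3k4 <- merge_intervals(h3k4, gap = cfg$h3k4_merge_gap)
  }
  if (!"peak_id" %in% names(h3k4)) {
    h3k4$peak_id <- sprintf("h3k4_%05d", seq_len(nrow(h3k4)))
  }
  out <- peaks %>% mutate(h3k4_partner = NA_character_,
                          h3k4_distance = NA_real_,
                          h3k4_partnered = FALSE)
  if (nrow(peaks) == 0 || nrow(h3k4) == 0) return(out)
  # suppressed: GRanges warns when the two sets share no chromosome, a
  # situation the partnered = FALSE default already covers
  near <- suppressWarnings(
    GenomicRanges::distanceToNearest(.as_gr(peaks), .as_gr(h3k4),
                                     ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(near)
  si <- S4Vectors::subjectHits(near)
  d <- S4Vectors::mcols(near)$distance
  out$h3k4_partner[qi] <- h3k4$peak_id[si]
  out$h3k4_distance[qi] <- d
  out$h3k4_partnered[qi] <- d <= cfg$h3k4_window
  out$h3k4_partner[!out$h3k4_partnered] <- NA_character_
  out
}

#' Pol II occupancy of genomic regions
#'
#' A region is Pol-II-positive when the number of tag 5' positions falling in
#' `[start, end)` strictly exceeds `polII_min_tags`.
#'
#' @param regions Interval tibble.
#' @param tags Tag-track tibble (`chrom`, `pos`), e.g. [read_tag_track()].
#' @param cfg A [pipeline_config()].
#' @return Logical vector, one element per region row.
#' @export
polII_occupancy <- function(regions, tags, cfg = pipeline_config()) {
  regions <- .validate_intervals(regions, "regions")
  if (nrow(regions) == 0) return(logical(0))
  counts <- numeric(nrow(regions))
  for (cn in unique(regions$chrom)) {
    pos <- sort(tags$pos[tags$chrom == cn])
    sel <- regions$chrom == cn
    if (length(pos) == 0) next
    counts[sel] <- findInterval(regions$end[sel] - 0.5, pos) -
      findInterval(regions$start[sel] - 0.5, pos)
  }
  counts > cfg$polII_min_tags
}

#' Link peaks to genes within a distance window
#'
#' A link exists when the edge-to-edge distance between the peak interval and
#' the gene span is at most `gene_link_window` (inclusive; 0 when the peak is
#' inside the gene). One peak may link several genes and vice versa.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return Tibble `peak_id`, `gene_id`, `distance`.
#' @export
link_peaks_to_genes <- function(peaks, genes, cfg = pipeline_config()) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(peak_id = character(), gene_id = character(),
                  distance = numeric()))
  }
  gp <- .as_gr(peaks)
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gp, gg, maxgap = cfg$gene_link_window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  tibble(peak_id = peaks$peak_id[qi],
         gene_id = genes$gene_id[si],
         distance = GenomicRanges::distance(gp[qi], gg[si],
                                            ignore.strand = TRUE)) %>%
    arrange(.data$peak_id, .data$gene_id)
}
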