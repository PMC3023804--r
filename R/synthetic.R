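## Seeded generators for every input the pipeline consumes, with planted
## ground truth emitted alongside. The paperlike preset builds a toy
## two-chromosome genome whose spatial layout guarantees the planted truth
## by construction: active gene zones hold the ChIP peaks and H3K4me3
## promoters; gene-free deserts inside active zones host the distant peaks;
## a peak-free zone holds regulated decoy genes (no peak within the link
## window); an inactive zone (promoters without H3K4me3, far from any
## active promoter) yields the unpartnered peaks.

.with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, force(code))
}

# Place `n` non-overlapping multi-exon genes inside [lo, hi) on one
# chromosome. Slot-based: equal pitch, gene placed with >= 6 kb clearance
# to slot edges, 3 exons.
.place_genes <- function(chrom, lo, hi, n, id_offset) {
  if (n == 0) return(NULL)
  pitch <- (hi - lo) / n
  if (pitch < 20000) {
    abort(sprintf("infeasible gene packing on %s: pitch %.0f < 20 kb",
                  chrom, pitch))
  }
  span_max <- min(24000, pitch - 12000)
  span <- runif(n, 8000, span_max)
  slack <- pitch - span - 12000
  start <- lo + (seq_len(n) - 1) * pitch + 6000 + runif(n) * slack
  start <- floor(start); span <- floor(span)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  purrr::map_dfr(seq_len(n), function(i) {
    s <- start[i]; w <- span[i]
    e1 <- floor(runif(1, 300, 800)); i1 <- floor(runif(1, 1000, 3000))
    e2 <- floor(runif(1, 500, 1500)); e3 <- floor(runif(1, 500, 1500))
    # genome-forward exon blocks; transcription order depends on strand
    if (strand[i] == "+") {
      ex <- tibble(start = s + c(0, e1 + i1, w - e3),
                   end = s + c(e1, e1 + i1 + e2, w))
    } else {
      ex <- tibble(start = s + c(0, w - e1 - i1 - e2, w - e1),
                   end = s + c(e3, w - e1 - i1, w))
    }
    tibble(gene_id = sprintf("G%04d", id_offset + i), chrom = chrom,
           strand = strand[i], start = s, end = s + w,
           exon_starts = list(ex$start), exon_ends = list(ex$end))
  })
}

# Expand placed genes into the standard gene-model tibble.
.models_from_placed <- function(placed) {
  exons <- placed %>%
    select("gene_id", "chrom", "strand", "exon_starts", "exon_ends") %>%
    tidyr::unnest(cols = c("exon_starts", "exon_ends")) %>%
    rename(start = "exon_starts", end = "exon_ends") %>%
    mutate(tx_id = paste0(.data$gene_id, ".t1"))
  suppressWarnings(.genes_from_exons(exons))
}

#' Generate a toy annotated genome
#'
#' Places non-overlapping three-exon genes on both strands, either uniformly
#' per chromosome or according to an explicit `layout` of placement regions.
#' Deterministic given `seed`.
#'
#' @param n_genes Total number of genes (split across chromosomes
#'   proportionally to length when `layout` is `NULL`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param seed Optional integer seed.
#' @param layout Optional tibble `chrom`, `lo`, `hi`, `n` of placement
#'   regions (overrides `n_genes`).
#' @return Gene-model tibble (as [read_gene_models()]) with attribute
#'   `tss`: a tibble `chrom`, `pos` of all TSS positions.
#' @export
generate_genome <- function(n_genes = 200,
                            chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                            seed = NULL, layout = NULL) {
  .with_seed_maybe(seed, {
    if (is.null(layout)) {
      share <- chrom_sizes / sum(chrom_sizes)
      n_per <- floor(n_genes * share)
      n_per[1] <- n_per[1] + n_genes - sum(n_per)
      layout <- tibble(chrom = names(chrom_sizes),
                       lo = 50000, hi = unname(chrom_sizes) - 50000,
                       n = as.integer(n_per))
    }
    offs <- cumsum(c(0, head(layout$n, -1)))
    placed <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      .place_genes(layout$chrom[i], layout$lo[i], layout$hi[i],
                   layout$n[i], offs[i])
    })
    if (is.null(placed) || nrow(placed) == 0) {
      genes <- tibble(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(), end = numeric(),
                      tss = numeric(), first_intron_end = numeric(),
                      tx_starts = list(), tx_ends = list(), tx3p = list())
    } else {
      genes <- .models_from_placed(placed)
    }
    attr(genes, "tss") <- genes %>% select("chrom", pos = "tss")
    genes
  })
}

# Sample planted anchor positions for one category relative to its genes.
# Returns positions guaranteed to categorise as planted under the default
# window definitions (forbidden = all gene spans + 5 kb flank strips).
# Upstream planting can fail for genes with crowded neighbourhoods; those
# entries come back NA so the caller can redraw the anchor gene.
.plant_anchor <- function(genes, gene_ids, category, forbidden,
                          chrom_sizes, cfg) {
  g <- genes[match(gene_ids, genes$gene_id), ]
  n <- nrow(g)
  if (category == "tss_flanking") {
    hi <- pmin(1500, abs(g$first_intron_end - g$tss) - 1)
    off <- floor(runif(n, -1000, hi))
    return(ifelse(g$strand == "+", g$tss + off, g$tss - off))
  }
  if (category == "intragenic") {
    pos <- numeric(n)
    for (i in seq_len(n)) {
      rng <- if (g$strand[i] == "+") c(g$first_intron_end[i], g$end[i] - 1)
             else c(g$start[i], g$first_intron_end[i])
      pos[i] <- floor(runif(1, rng[1], rng[2]))
    }
    return(pos)
  }
  if (category == "upstream") {
    pos <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      strip <- if (g$strand[i] == "+") {
        tibble(chrom = g$chrom[i], start = g$tss[i] - cfg$upstream_max,
               end = g$tss[i] - cfg$tss_flank_upstream)
      } else {
        tibble(chrom = g$chrom[i], start = g$tss[i] + cfg$tss_flank_upstream + 1,
               end = g$tss[i] + cfg$upstream_max + 1)
      }
      allowed <- .interval_setdiff(strip, forbidden, chrom_sizes)
      if (total_bp(allowed) > 0) pos[i] <- .sample_positions(allowed, 1)
    }
    return(pos)
  }
  abort("unknown category")
}

#' Generate ChIP peak tables with planted truth
#'
#' Plants peaks of known genomic category anchored at designated genes,
#' H3K4me3 peaks at the promoters of active genes, and a Pol II tag track
#' exceeding the occupancy bound exactly for designated genes. Peak quality
#' (FDR / control tags) is mixed so a known subset is high-confidence.
#'
#' @param genes Gene-model tibble from [generate_genome()].
#' @param chrom_sizes Named chromosome lengths.
#' @param quota Named counts per planted category
#'   (`tss_flanking`, `intragenic`, `upstream`, `distant`).
#' @param anchor_genes Gene ids eligible to anchor gene-proximal peaks.
#' @param must_hit_genes Gene ids guaranteed at least one `tss_flanking` or
#'   `intragenic` peak (the future target genes).
#' @param distant_regions Interval tibble from which distant anchors are
#'   drawn (must already respect the category definition).
#' @param active_genes Gene ids whose promoters carry an H3K4me3 peak.
#' @param frac_low_quality Fraction of gene-proximal peaks planted as
#'   low-quality (failing the FDR or the control-tag bound).
#' @param polII_positive_fraction Fraction of active genes planted Pol II
#'   positive.
#' @param cfg A [pipeline_config()] (window definitions used for planting).
#' @param seed Optional integer seed.
#' @return List `peaks`, `h3k4`, `polII_tags`, `truth` (per-peak planted
#'   category, anchor gene, high-confidence flag, partnered flag) and
#'   `gene_truth` (per active gene: Pol II flag).
#' @export
generate_peaks <- function(genes, chrom_sizes,
                           quota = c(tss_flanking = 147, intragenic = 57,
                                     upstream = 30, distant = 66),
                           anchor_genes = genes$gene_id,
                           must_hit_genes = character(),
                           distant_regions = NULL,
                           active_genes = genes$gene_id,
                           frac_low_quality = 0.2,
                           polII_positive_fraction = 0.7,
                           cfg = pipeline_config(), seed = NULL) {
  .with_seed_maybe(seed, {
    stopifnot(all(names(quota) %in% c("tss_flanking", "intragenic",
                                      "upstream", "distant")))
    full <- c(tss_flanking = 0, intragenic = 0, upstream = 0, distant = 0)
    full[names(quota)] <- quota
    quota <- full
    forbidden <- bind_rows(
      genes %>% select("chrom", "start", "end"),
      genes %>% mutate(
        start = if_else(.data$strand == "+",
                        .data$tss - cfg$tss_flank_upstream, .data$tss + 1),
        end = if_else(.data$strand == "+", .data$tss,
                      .data$tss + cfg$tss_flank_upstream + 1)) %>%
        select("chrom", "start", "end")
    ) %>% merge_intervals()
    # assign anchor genes: must-hit genes first (flank/intragenic slots)
    n_prox <- quota[c("tss_flanking", "intragenic", "upstream")]
    if (length(must_hit_genes) > sum(n_prox[c("tss_flanking", "intragenic")])) {
      abort("quota too small for the must-hit gene set")
    }
    slots <- rep(names(n_prox), n_prox)
    anchors <- character(length(slots))
    mh <- which(slots != "upstream")[seq_along(must_hit_genes)]
    anchors[mh] <- must_hit_genes
    rest <- setdiff(seq_along(slots), mh)
    anchors[rest] <- sample(anchor_genes, length(rest), replace = TRUE)
    prox <- tibble(category = slots, anchor_gene_id = anchors)
    prox$pos <- NA_real_
    for (cat in unique(prox$category)) {
      sel <- prox$category == cat
      prox$pos[sel] <- .plant_anchor(genes, prox$anchor_gene_id[sel], cat,
                                     forbidden, chrom_sizes, cfg)
    }
    # redraw crowded upstream anchors (bounded)
    for (try in 1:50) {
      bad <- which(is.na(prox$pos))
      if (length(bad) == 0) break
      prox$anchor_gene_id[bad] <- sample(anchor_genes, length(bad),
                                         replace = TRUE)
      prox$pos[bad] <- .plant_anchor(genes, prox$anchor_gene_id[bad],
                                     "upstream", forbidden, chrom_sizes, cfg)
    }
    if (any(is.na(prox$pos))) abort("could not place all upstream peaks")
    prox$chrom <- genes$chrom[match(prox$anchor_gene_id, genes$gene_id)]
    n_dist <- unname(quota["distant"])
    dist_tbl <- NULL
    if (!is.na(n_dist) && n_dist > 0) {
      if (is.null(distant_regions) || total_bp(distant_regions) == 0) {
        abort("distant peaks requested but no distant regions supplied")
      }
      m <- merge_intervals(distant_regions)
      w <- m$end - m$start
      i <- sample.int(nrow(m), n_dist, replace = TRUE, prob = w / sum(w))
      pos <- floor(m$start[i] + runif(n_dist) * w[i])
      dist_tbl <- tibble(category = "distant", anchor_gene_id = NA_character_,
                         pos = pos, chrom = m$chrom[i])
    }
    plan <- bind_rows(prox, dist_tbl)
    n <- nrow(plan)
    width <- floor(runif(n, 400, 1000))
    summit <- floor(width / 2)
    start <- plan$pos - summit
    low <- runif(n) < frac_low_quality
    fdr <- ifelse(low, runif(n, 0.05, 0.6), runif(n, 0, 0.0499))
    ctl <- ifelse(low & runif(n) < 0.5, floor(runif(n, 100, 400)),
                  floor(runif(n, 0, 100)))
    # a low-quality peak must fail at least one bound
    fix <- low & fdr < cfg$fdr_max & ctl < cfg$control_tags_max
    fdr[fix] <- runif(sum(fix), 0.05, 0.6)
    # must-hit peaks are always high confidence
    keep_hc <- plan$anchor_gene_id %in% must_hit_genes
    fdr[keep_hc] <- runif(sum(keep_hc), 0, 0.0499)
    ctl[keep_hc] <- floor(runif(sum(keep_hc), 0, 100))
    ord <- sample.int(n)  # shuffle so category order carries no signal
    p_start <- start[ord]
    p_end <- start[ord] + width[ord]
    peaks <- tibble(
      peak_id = sprintf("peak_%05d", seq_len(n)),
      chrom = plan$chrom[ord], start = p_start,
      end = p_end, summit = summit[ord],
      tag_count = floor(runif(n, 60, 400)),
      fold_enrichment = runif(n, 5, 40), fdr = fdr[ord],
      control_tags = ctl[ord])
    active <- genes %>% filter(.data$gene_id %in% active_genes)
    h3k4_w <- floor(runif(nrow(active), 800, 1200))
    h3k4 <- tibble(
      peak_id = sprintf("h3k4_%05d", seq_len(nrow(active))),
      chrom = active$chrom,
      start = active$tss - h3k4_w %/% 2,
      end = active$tss + h3k4_w %/% 2,
      summit = h3k4_w %/% 2, tag_count = floor(runif(nrow(active), 80, 300)),
      fold_enrichment = runif(nrow(active), 8, 50),
      fdr = runif(nrow(active), 0, 0.01),
      control_tags = floor(runif(nrow(active), 0, 50)),
      gene_id = active$gene_id)
    pol_pos <- runif(nrow(active)) < polII_positive_fraction
    polII_tags <- purrr::map_dfr(seq_len(nrow(active)), function(i) {
      k <- if (pol_pos[i]) floor(runif(1, 51, 120)) else floor(runif(1, 0, 51))
      if (k == 0) return(NULL)
      tibble(chrom = h3k4$chrom[i],
             pos = floor(runif(k, h3k4$start[i], h3k4$end[i])))
    })
    if (nrow(polII_tags) == 0) {
      polII_tags <- tibble(chrom = character(), pos = numeric())
    }
    polII_tags <- polII_tags %>% arrange(.data$chrom, .data$pos)
    partnered <- rep(FALSE, n)
    if (nrow(h3k4) > 0) {
      ni <- .nearest_interval(peaks, h3k4)
      ok <- !is.na(ni)
      partnered[ok] <- interval_distance(peaks[ok, ], h3k4[ni[ok], ]) <=
        cfg$h3k4_window
    }
    truth <- tibble(
      peak_id = peaks$peak_id,
      category = plan$category[ord],
      anchor_gene_id = plan$anchor_gene_id[ord],
      high_confidence = peaks$fdr < cfg$fdr_max &
        peaks$control_tags < cfg$control_tags_max,
      h3k4_partnered = partnered)
    gene_truth <- tibble(gene_id = active$gene_id,
                         polII_positive = pol_pos,
                         h3k4_peak_id = h3k4$peak_id)
    list(peaks = peaks, h3k4 = h3k4 %>% select(-"gene_id"),
         polII_tags = polII_tags, truth = truth, gene_truth = gene_truth)
  })
}

# index of nearest interval in `subject` for each row of `query`
# (same-chromosome edge distance; arbitrary but deterministic on ties)
.nearest_interval <- function(query, subject) {
  near <- GenomicRanges::distanceToNearest(.as_gr(query), .as_gr(subject),
                                           ignore.strand = TRUE)
  idx <- rep(NA_integer_, nrow(query))
  idx[S4Vectors::queryHits(near)] <- S4Vectors::subjectHits(near)
  idx
}

#' Generate expression tables, probe alignments and planted responses
#'
#' Plants fold changes with clear margins around the regulation thresholds
#' so that, at `noise_sd = 0`, classification recovers every planted label.
#' Probes exercise assignment rules 1, 2, 3 and 9 plus unaligned probes.
#'
#' @param genes Gene-model tibble.
#' @param target_genes Gene ids carrying the planted responses.
#' @param response_quota Named counts over `type_I`, `type_II`, `type_III`
#'   assigned to `target_genes` in order (must sum to
#'   `length(target_genes)`).
#' @param decoy_regulated Gene ids regulated but (by layout) peak-free.
#' @param no_probe_genes Gene ids whose only probe fails the intensity gate.
#' @param noise_sd Multiplicative log2-scale noise on fold changes.
#' @param cfg A [pipeline_config()].
#' @param seed Optional integer seed.
#' @return List `expression`, `alignments`, `all_probe_ids`, `truth`
#'   (per gene: planted response or `unregulated`, target flag).
#' @export
generate_expression <- function(genes, target_genes,
                                response_quota = c(type_I = 25, type_II = 14,
                                                   type_III = 14),
                                decoy_regulated = character(),
                                no_probe_genes = character(),
                                noise_sd = 0, cfg = pipeline_config(),
                                seed = NULL) {
  .with_seed_maybe(seed, {
    if (sum(response_quota) != length(target_genes)) {
      abort("response quota must sum to the number of target genes")
    }
    draw_fc <- function(resp) {
      switch(resp,
        type_I = c(runif(1, 1.8, 3.2), runif(1, 0.92, 1.12)),
        type_II = c(runif(1, 1.8, 3.2), runif(1, 1.35, 2.2)),
        type_III = c(runif(1, 0.35, 0.55), runif(1, 0.9, 1.3)),
        ligand_only = c(runif(1, 0.8, 1.25), runif(1, 1.35, 2.0)),
        unregulated = c(runif(1, 0.78, 1.28), runif(1, 0.88, 1.14)))
    }
    resp <- rep(names(response_quota), response_quota)
    plan <- tibble(gene_id = genes$gene_id) %>%
      mutate(planted_response = dplyr::case_when(
        .data$gene_id %in% target_genes ~
          resp[match(.data$gene_id, target_genes)],
        .data$gene_id %in% decoy_regulated ~
          sample(c("type_I", "type_II", "type_III", "ligand_only"),
                 n(), replace = TRUE),
        TRUE ~ "unregulated"),
        is_target = .data$gene_id %in% target_genes)
    plan$planted_response[plan$gene_id %in% no_probe_genes] <- "unregulated"
    # probes: one primary per gene; ~40% of genes get a weaker secondary
    fcs <- t(vapply(plan$planted_response, draw_fc, numeric(2)))
    primary <- tibble(
      probe_id = sprintf("P_%s_1", plan$gene_id), gene_id = plan$gene_id,
      avg_log_intensity = if_else(plan$gene_id %in% no_probe_genes,
                                  runif(nrow(plan), 3, 5.5),
                                  runif(nrow(plan), 6.5, 12)),
      fc_sirna = fcs[, 1], fc_ligand = fcs[, 2])
    sec_sel <- runif(nrow(plan)) < 0.4 & !plan$gene_id %in% no_probe_genes
    secondary <- primary[sec_sel, ] %>%
      mutate(probe_id = sprintf("P_%s_2", .data$gene_id),
             avg_log_intensity = pmax(6.2, .data$avg_log_intensity - 1),
             fc_sirna = .data$fc_sirna^0.5, fc_ligand = .data$fc_ligand^0.5)
    expr <- bind_rows(primary, secondary)
    if (noise_sd > 0) {
      expr <- expr %>%
        mutate(fc_sirna = .data$fc_sirna * 2^rnorm(n(), 0, noise_sd),
               fc_ligand = .data$fc_ligand * 2^rnorm(n(), 0, noise_sd))
    }
    # alignments: default rule 1 (perfect transcript hit, single gene)
    aln <- expr %>%
      mutate(target = "transcript", chrom = NA_character_,
             start = NA_real_, end = NA_real_, mismatches = 0L,
             within_2kb_3prime = TRUE) %>%
      select("probe_id", "target", "chrom", "start", "end", "mismatches",
             "gene_id", "within_2kb_3prime")
    # rule 2: first targets' primaries also hit a neighbour transcript,
    # resolved by the 3'-proximity flag
    r2 <- head(target_genes, 6)
    if (length(r2) > 0) {
      other <- sample(setdiff(genes$gene_id, r2), length(r2))
      aln <- bind_rows(aln, tibble(
        probe_id = sprintf("P_%s_1", r2), target = "transcript",
        chrom = NA_character_, start = NA_real_, end = NA_real_,
        mismatches = 0L, gene_id = other, within_2kb_3prime = FALSE))
    }
    # rule 3 probes: perfect genomic hits inside two different genes
    g3 <- genes %>% filter(!.data$gene_id %in% target_genes) %>% head(8)
    r3 <- purrr::map_dfr(1:4, function(i) {
      gg <- g3[c(2 * i - 1, 2 * i), ]
      tibble(probe_id = sprintf("P_multi_%d", i), target = "genome",
             chrom = gg$chrom,
             start = floor((gg$start + gg$end) / 2),
             end = floor((gg$start + gg$end) / 2) + 60,
             mismatches = 0L, gene_id = NA_character_,
             within_2kb_3prime = NA)
    })
    # rule 9 probes: mismatch-only transcript hits to one (decoy) gene
    g9 <- genes %>%
      filter(!.data$gene_id %in% c(target_genes, decoy_regulated)) %>%
      tail(3)
    r9 <- tibble(probe_id = sprintf("P_mm_%d", 1:3), target = "transcript",
                 chrom = NA_character_, start = NA_real_, end = NA_real_,
                 mismatches = 2L, gene_id = g9$gene_id,
                 within_2kb_3prime = TRUE)
    aln <- bind_rows(aln, r3, r9)
    extra_expr <- tibble(
      probe_id = c(r3$probe_id[!duplicated(r3$probe_id)], r9$probe_id,
                   "P_orphan_1", "P_orphan_2"),
      gene_id = NA_character_,
      avg_log_intensity = runif(9, 6.5, 10),
      fc_sirna = runif(9, 0.8, 1.25), fc_ligand = runif(9, 0.9, 1.15))
    expr <- bind_rows(expr, extra_expr) %>% select(-"gene_id")
    list(expression = expr %>% arrange(.data$probe_id),
         alignments = aln %>% arrange(.data$probe_id, .data$target),
         all_probe_ids = sort(unique(c(aln$probe_id, expr$probe_id))),
         truth = plan)
  })
}

#' Generate a trait-SNP catalog with one planted enriched trait
#'
#' The planted trait's SNPs fall within the extension flank of randomly
#' chosen query peaks; the remaining traits are placed by the package's own
#' null sampler (anchor TSS uniform, TSS distances preserved), so they are
#' draws from the enrichment test's null model.
#'
#' @param query_peaks Peak tibble the planted trait should be enriched near.
#' @param tss TSS tibble (`chrom`, `pos`).
#' @param chrom_sizes Named chromosome lengths.
#' @param n_traits Total traits (>= 2); one is planted.
#' @param snps_per_trait SNPs per trait.
#' @param planted_fraction Fraction of the planted trait's SNPs placed near
#'   peaks (the rest follow the null sampler).
#' @param max_offset Maximum |offset| (bp) of a planted SNP from its peak
#'   anchor; keep below the test's flank so planted SNPs always hit.
#' @param seed Optional integer seed.
#' @return List `snps` (tibble `trait`, `chrom`, `pos`) and `truth`
#'   (planted trait name).
#' @export
generate_snp_catalog <- function(query_peaks, tss, chrom_sizes,
                                 n_traits = 10, snps_per_trait = 30,
                                 planted_fraction = 1, max_offset = 150000,
                                 seed = NULL) {
  .with_seed_maybe(seed, {
    stopifnot(n_traits >= 2)
    anchor <- .peak_anchor(query_peaks)
    k <- snps_per_trait
    n_near <- round(planted_fraction * k)
    pick <- sample.int(nrow(query_peaks), n_near, replace = TRUE)
    pos <- anchor[pick] + floor(runif(n_near, -max_offset, max_offset))
    pos <- pmin(pmax(pos, 0), unname(chrom_sizes[query_peaks$chrom[pick]]) - 1)
    planted <- tibble(trait = "planted_trait",
                      chrom = query_peaks$chrom[pick], pos = pos)
    null_one <- function(trait_name, template) {
      q <- template %>% mutate(start = .data$pos, end = .data$pos + 1) %>%
        select("chrom", "start", "end")
      s <- sample_null_query(q, tss, chrom_sizes)
      tibble(trait = trait_name, chrom = s$chrom, pos = s$start)
    }
    if (n_near < k) {
      planted <- bind_rows(planted,
                           null_one("planted_trait",
                                    tibble(chrom = sample(names(chrom_sizes),
                                                          k - n_near,
                                                          replace = TRUE),
                                           pos = floor(runif(k - n_near, 1e5,
                                                             5e5)))))
    }
    nulls <- purrr::map_dfr(seq_len(n_traits - 1), function(i) {
      null_one(sprintf("null_trait_%02d", i), planted[seq_len(k), ])
    })
    list(snps = bind_rows(planted, nulls) %>%
           arrange(.data$trait, .data$chrom, .data$pos),
         truth = "planted_trait")
  })
}

#' Synthesise a complete paperlike study with planted truth
#'
#' Composes the genome, peak, expression and SNP generators into the full
#' input bundle the pipeline consumes. The paperlike preset: 2 chromosomes
#' of 5 Mb, 200 genes, 300 ChIP peaks with category mix 49/19/10/22%,
#' 80% high-confidence, ~94% of high-confidence peaks partnered to an
#' H3K4me3 promoter, 70% of active genes Pol II positive, 53 planted target
#' genes with response quota 25/14/14 (type I/II/III), 10 regulated
#' peak-free decoy genes, and a 10-trait SNP catalog with one fully planted
#' enriched trait.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param noise_sd Multiplicative log2 noise on expression fold changes
#'   (0 = noise-free planted truth).
#' @param n_traits,snps_per_trait SNP catalog dimensions.
#' @param cfg A [pipeline_config()].
#' @return List with `genes`, `tss`, `chrom_sizes`, `peaks`, `h3k4`,
#'   `polII_tags`, `expression`, `alignments`, `all_probe_ids`, `snps`,
#'   `config` and `truth` (peak truth, gene truth, expression truth,
#'   planted trait, parameter record).
#' @export
synthesize_study <- function(seed = 1, noise_sd = 0, n_traits = 10,
                             snps_per_trait = 30, cfg = pipeline_config()) {
  chrom_sizes <- c(chr1 = 5e6, chr2 = 5e6)
  deserts <- tibble(chrom = c("chr1", "chr1", "chr2", "chr2"),
                    start = c(1.0e6, 2.2e6, 1.1e6, 2.3e6),
                    end = c(1.2e6, 2.4e6, 1.3e6, 2.5e6))
  # explicit placement regions: active peak zones exclude the deserts;
  # chr1 tail = peak-free decoy zone, chr2 tail = inactive zone
  layout <- tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1",
              "chr2", "chr2", "chr2", "chr2"),
    lo = c(5.0e4, 1.2e6, 2.4e6, 3.80e6,
           5.0e4, 1.3e6, 2.5e6, 3.75e6),
    hi = c(1.0e6, 2.2e6, 3.45e6, 4.95e6,
           1.1e6, 2.3e6, 3.30e6, 4.95e6),
    n = c(27, 28, 30, 25,
          28, 27, 25, 10),
    zone = c("active", "active", "active", "peak_free",
             "active", "active", "active", "inactive"))
  withr::with_seed(seed, {
    genes <- generate_genome(chrom_sizes = chrom_sizes,
                             layout = layout[c("chrom", "lo", "hi", "n")])
    tss <- attr(genes, "tss")
    # gene ids were assigned region by region in layout order
    zone_lookup <- setNames(rep(layout$zone, layout$n),
                            sprintf("G%04d", seq_len(sum(layout$n))))
    genes$zone <- unname(zone_lookup[genes$gene_id])
    active_ids <- genes$gene_id[genes$zone %in% c("active", "peak_free")]
    peak_anchor_ids <- genes$gene_id[genes$zone == "active"]
    inactive_ids <- genes$gene_id[genes$zone == "inactive"]
    decoy_pool <- genes$gene_id[genes$zone == "peak_free"]
    target_genes <- sample(peak_anchor_ids, 53)
    # distant anchors: desert interiors (>25 kb clear of any TSS by layout)
    distant_regions <- deserts %>%
      mutate(start = .data$start + 26000, end = .data$end - 26000)
    active_part <- generate_peaks(
      genes, chrom_sizes,
      quota = c(tss_flanking = 141, intragenic = 52, upstream = 26,
                distant = 66),
      anchor_genes = setdiff(peak_anchor_ids, target_genes),
      must_hit_genes = target_genes,
      distant_regions = distant_regions,
      active_genes = active_ids,
      frac_low_quality = 0.26, polII_positive_fraction = 0.7, cfg = cfg)
    inactive_part <- generate_peaks(
      genes, chrom_sizes,
      quota = c(tss_flanking = 6, intragenic = 5, upstream = 4, distant = 0),
      anchor_genes = inactive_ids, must_hit_genes = character(),
      distant_regions = NULL, active_genes = character(),
      frac_low_quality = 0, polII_positive_fraction = 0, cfg = cfg)
    renum <- function(p, off, prefix = "peak") {
      p %>% mutate(peak_id = sprintf("%s_%05d", prefix,
                                     off + seq_len(nrow(p))))
    }
    n_act <- nrow(active_part$peaks)
    peaks <- bind_rows(renum(active_part$peaks, 0),
                       renum(inactive_part$peaks, n_act))
    peak_truth <- bind_rows(renum(active_part$truth, 0),
                            renum(inactive_part$truth, n_act))
    h3k4 <- active_part$h3k4
    polII_tags <- active_part$polII_tags
    expr_part <- generate_expression(
      genes, target_genes,
      response_quota = c(type_I = 25, type_II = 14, type_III = 14),
      decoy_regulated = sample(decoy_pool, 10),
      no_probe_genes = sample(setdiff(peak_anchor_ids,
                                      target_genes), 5),
      noise_sd = noise_sd, cfg = cfg)
    hc_partnered <- peaks[peak_truth$high_confidence &
                            peak_truth$h3k4_partnered, ]
    snp_part <- generate_snp_catalog(hc_partnered, tss, chrom_sizes,
                                     n_traits = n_traits,
                                     snps_per_trait = snps_per_trait)
    list(genes = genes, tss = tss, chrom_sizes = chrom_sizes,
         peaks = peaks, h3k4 = h3k4, polII_tags = polII_tags,
         expression = expr_part$expression,
         alignments = expr_part$alignments,
         all_probe_ids = expr_part$all_probe_ids,
         snps = snp_part$snps, config = cfg,
         truth = list(peaks = peak_truth,
                      genes = active_part$gene_truth,
                      expression = expr_part$truth,
                      target_genes = sort(target_genes),
                      planted_trait = snp_part$truth,
                      seed = seed, noise_sd = noise_sd))
  })
}
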