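## The 16-rule probe-to-gene assignment cascade.
##
## A probe's alignment evidence is split into perfect (0 mismatches) and
## mismatched records. Perfect evidence is consumed by rules 1-8, mismatched
## evidence by the mirrored rules 9-16; a probe with any perfect evidence is
## decided entirely by it. Within a block the rules are, in order:
##   1/9  transcript hits to a single gene               -> that gene
##   2/10 transcript hits to several genes, exactly one
##        with a hit within 2 kb of a transcript 3' end  -> that gene
##   3/11 genomic hits inside different genes            -> none
##   4/12 genomic hit(s) inside exactly one gene         -> that gene
##   5/13 one genomic location covered by several genes  -> all covering genes
##   6/14 genomic hit outside genes, transcript hits to
##        several genes                                  -> none (candidates kept)
##   7/15 genomic hit within 2 kb of exactly one gene    -> that gene
##   8/16 genomic hit outside any gene region            -> none
## Probes with no alignments at all get rule 16 and are flagged unaligned.

# Annotate genomic alignment records with covering / nearby gene sets.
.annotate_genomic_hits <- function(aln, genes, window) {
  aln$covering <- vector("list", nrow(aln))
  aln$near <- vector("list", nrow(aln))
  gidx <- which(aln$target == "genome" & !is.na(aln$chrom))
  if (length(gidx) == 0 || nrow(genes) == 0) return(aln)
  ga <- aln[gidx, ]
  gr_a <- GenomicRanges::GRanges(ga$chrom, IRanges::IRanges(ga$start + 1, ga$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_g, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  inside <- ga$start[qi] < genes$end[si] & ga$end[qi] > genes$start[si]
  cov_split <- split(genes$gene_id[si][inside], qi[inside])
  near_split <- split(genes$gene_id[si][!inside], qi[!inside])
  for (k in names(cov_split)) aln$covering[[gidx[as.integer(k)]]] <- cov_split[[k]]
  for (k in names(near_split)) aln$near[[gidx[as.integer(k)]]] <- near_split[[k]]
  aln
}

.assign_one <- function(df, base) {
  t_hits <- df[df$target == "transcript", ]
  g_hits <- df[df$target == "genome", ]
  t_genes <- unique(t_hits$gene_id[!is.na(t_hits$gene_id)])
  res <- function(rule, genes = character(), candidates = character()) {
    list(rule = base + rule, gene_ids = sort(genes),
         candidates = sort(candidates))
  }
  if (nrow(t_hits) > 0 && length(t_genes) == 1) return(res(1L, t_genes))
  if (length(t_genes) > 1) {
    g3 <- unique(t_hits$gene_id[!is.na(t_hits$within_2kb_3prime) &
                                  t_hits$within_2kb_3prime])
    if (length(g3) == 1) return(res(2L, g3))
  }
  cov_sets <- g_hits$covering
  cov_n <- lengths(cov_sets)
  in_gene <- cov_n > 0
  genes_covered <- unique(unlist(cov_sets))
  if (sum(in_gene) >= 2 && length(genes_covered) >= 2) return(res(3L))
  if (length(genes_covered) == 1) return(res(4L, genes_covered))
  if (sum(in_gene) == 1 && length(genes_covered) >= 2) {
    return(res(5L, genes_covered))
  }
  # no genomic hit inside a gene from here on
  if (length(t_genes) >= 2) return(res(6L, candidates = t_genes))
  near_genes <- unique(unlist(g_hits$near))
  if (length(near_genes) == 1) return(res(7L, near_genes))
  res(8L)
}

#' Assign microarray probes to genes
#'
#' Runs the 16-rule priority cascade over all alignment records of each
#' probe. The first rule whose condition holds decides the assignment;
#' rules 3, 8, 11 and 16 (and, by this package's reading, 6 and 14) assign
#' no gene. Alignment-record order never affects the outcome.
#'
#' @param alignments Alignment-record tibble (see
#'   [read_probe_alignments()]): `probe_id`, `target`
#'   (`"transcript"`/`"genome"`), `chrom`, `start`, `end`, `mismatches`,
#'   `gene_id` (transcript hits), `within_2kb_3prime` (transcript hits).
#' @param genes Gene-model tibble; used to resolve which genes cover or lie
#'   within 2 kb of genomic hits.
#' @param cfg A [pipeline_config()] (uses `probe_3prime_window`).
#' @param all_probe_ids Optional character vector of every probe on the
#'   array; probes without any alignment record get rule 16 with no gene and
#'   `unaligned = TRUE`.
#' @return Tibble with one row per distinct probe: `probe_id`, `rule`
#'   (1-16), `gene_ids` (list-column, possibly empty), `candidates`
#'   (list-column, non-empty only for rules 6/14), `unaligned`.
#' @export
assign_probes <- function(alignments, genes, cfg = pipeline_config(),
                          all_probe_ids = NULL) {
  aln <- as_tibble(alignments)
  if (!"gene_id" %in% names(aln)) aln$gene_id <- NA_character_
  if (!"within_2kb_3prime" %in% names(aln)) aln$within_2kb_3prime <- NA
  if (!"chrom" %in% names(aln)) aln$chrom <- NA_character_
  if (nrow(aln) > 0 && any(is.na(aln$mismatches))) {
    abort("alignment records must carry a mismatch count")
  }
  aln <- .annotate_genomic_hits(aln, genes, cfg$probe_3prime_window)
  by_probe <- split(aln, aln$probe_id)
  rows <- purrr::imap(by_probe, function(df, pid) {
    perfect <- df[df$mismatches == 0, ]
    r <- if (nrow(perfect) > 0) .assign_one(perfect, 0L)
         else .assign_one(df, 8L)
    tibble(probe_id = pid, rule = r$rule, gene_ids = list(r$gene_ids),
           candidates = list(r$candidates), unaligned = FALSE)
  })
  out <- bind_rows(rows)
  missing <- setdiff(all_probe_ids, out$probe_id)
  if (length(missing) > 0) {
    out <- bind_rows(out, tibble(
      probe_id = missing, rule = 16L,
      gene_ids = rep(list(character()), length(missing)),
      candidates = rep(list(character()), length(missing)),
      unaligned = TRUE))
  }
  if (nrow(out) == 0) {
    out <- tibble(probe_id = character(), rule = integer(),
                  gene_ids = list(), candidates = list(),
                  unaligned = logical())
  }
  out %>% arrange(.data$probe_id)
}

#' Assign all probes and tally rule usage
#'
#' Convenience wrapper around [assign_probes()] that also returns the
#' rule-usage histogram.
#'
#' @inheritParams assign_probes
#' @return List with `assignments` (as [assign_probes()]) and `histogram`
#'   (tibble `rule`, `n`; sums to the number of distinct probes).
#' @export
assign_all <- function(alignments, genes, cfg = pipeline_config()) {
  asg <- assign_probes(alignments, genes, cfg)
  hist <- asg %>% count(.data$rule, name = "n")
  list(assignments = asg, histogram = hist)
}

#' Pick the representative probe of a gene
#'
#' Among probes passing the intensity gate, returns the most strongly
#' regulated one: the probe maximising `max(|log2 fc_sirna|, |log2
#' fc_ligand|)`. Ties are broken by higher averaged intensity, then by
#' probe id.
#'
#' @param expr Expression tibble restricted to the probes of one gene
#'   (`probe_id`, `avg_log_intensity`, `fc_sirna`, `fc_ligand`).
#' @param cfg A [pipeline_config()] (uses `intensity_min`).
#' @return The representative `probe_id`, or `NA_character_` when no probe
#'   passes the intensity gate.
#' @export
select_representative_probe <- function(expr, cfg = pipeline_config()) {
  ok <- expr %>% filter(.data$avg_log_intensity >= cfg$intensity_min)
  if (nrow(ok) == 0) return(NA_character_)
  ok %>%
    mutate(score = pmax(abs(log2(.data$fc_sirna)), abs(log2(.data$fc_ligand)))) %>%
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$avg_log_intensity),
            .data$probe_id) %>%
    pull("probe_id") %>%
    first()
}
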