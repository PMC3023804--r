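## Readers and writers for the standard inputs: MACS-style peak tables,
## tag tracks (BED), gene models (GFF3 / BED12 / TSV), probe alignment
## records, expression tables, SNP catalogs and chromosome sizes.
## Everything is returned as a tibble in internal 0-based half-open
## coordinates; 1-based sources are shifted at this boundary only.

#' Read a MACS-style peak table
#'
#' Expects a tab-separated file with a header. Mandatory columns: `chrom`,
#' `start`, `end`. Recognised optional columns: `peak_id`, `summit` (offset
#' from `start`), `tag_count`, `fold_enrichment`, `fdr`, `control_tags`.
#' Missing optional columns are filled with `NA`.
#'
#' @param path File path.
#' @param coords `"bed"` when the file is already 0-based half-open,
#'   `"one_based"` when start/end are 1-based inclusive (MACS XLS dialect);
#'   the latter are converted on read.
#' @return Tibble of peaks in internal coordinates.
#' @export
read_peak_table <- function(path, coords = c("bed", "one_based")) {
  coords <- match.arg(coords)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("peak table `%s` is missing mandatory column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  for (col in c("start", "end", "summit", "tag_count", "fold_enrichment",
                "fdr", "control_tags")) {
    if (col %in% names(x) && !is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))) &
                     !is.na(x[[col]]))
      abort(sprintf("peak table `%s`: non-numeric `%s` at line(s) %s",
                    path, col,
                    paste(head(bad + 1L, 5), collapse = ", ")))
    }
  }
  if (coords == "one_based") x$start <- x$start - 1
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("peak table `%s`: start >= end at line(s) %s", path,
                  paste(head(bad + 1L, 5), collapse = ", ")))
  }
  if (!"peak_id" %in% names(x)) x$peak_id <- sprintf("peak_%05d", seq_len(nrow(x)))
  for (col in c("summit", "tag_count", "fold_enrichment", "fdr", "control_tags")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  if (any(!is.na(x$summit) & (x$summit < 0 | x$summit >= x$end - x$start))) {
    abort(sprintf("peak table `%s`: summit offset outside peak", path))
  }
  as_tibble(x)[c("peak_id", "chrom", "start", "end", "summit", "tag_count",
                 "fold_enrichment", "fdr", "control_tags")]
}

#' Write a peak table
#'
#' Tab-separated, header, internal 0-based half-open coordinates.
#' `read_peak_table(write_peak_table(x))` is the identity.
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}

#' Read a tag track (mapped read 5' ends) from BED
#'
#' BED3-BED6 without header. The tag position is the 5' end of the read:
#' `start` for `+` (or unstranded) records, `end - 1` for `-` records.
#'
#' @param path BED file.
#' @param label Optional track label (e.g. `"PolII"`, `"IgG"`).
#' @return Tibble `chrom`, `pos`, `label`, sorted within chromosome.
#' @export
read_tag_track <- function(path, label = NA_character_) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 3) abort(sprintf("`%s` is not BED3+", path))
  strand <- if (ncol(x) >= 6) x[[6]] else rep("+", nrow(x))
  pos <- ifelse(strand == "-", x[[3]] - 1, x[[2]])
  tibble(chrom = as.character(x[[1]]), pos = as.numeric(pos), label = label) %>%
    arrange(.data$chrom, .data$pos)
}

#' Write a tag track as BED3
#' @param tags Tibble `chrom`, `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_track <- function(tags, path) {
  readr::write_tsv(tags %>% mutate(end = .data$pos + 1) %>%
                     select("chrom", "pos", "end"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Build the gene-model tibble from per-transcript exon tables.
# exons: tibble(gene_id, tx_id, chrom, strand, start, end) 0-based half-open.
.genes_from_exons <- function(exons, reference = c("most_5prime", "longest")) {
  reference <- match.arg(reference)
  tx <- exons %>%
    group_by(.data$gene_id, .data$tx_id, .data$chrom, .data$strand) %>%
    summarise(tx_start = min(.data$start), tx_end = max(.data$end),
              n_exons = n(), .groups = "drop") %>%
    mutate(tss = if_else(.data$strand == "+", .data$tx_start, .data$tx_end - 1),
           tx3p = if_else(.data$strand == "+", .data$tx_end - 1, .data$tx_start))
  single <- tx$n_exons == 1
  if (any(single)) {
    warn(sprintf(
      "%d single-exon transcript(s): first_intron_end falls back to the end of the first exon",
      sum(single)))
  }
  genes <- tx %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$tx_start), end = max(.data$tx_end),
              tx_starts = list(.data$tx_start), tx_ends = list(.data$tx_end),
              tx3p = list(.data$tx3p),
              ref_tx = {
                o <- if (first(.data$strand) == "+") {
                  order(.data$tss, .data$tx_id)
                } else order(-.data$tss, .data$tx_id)
                if (reference == "longest") {
                  o <- order(-(.data$tx_end - .data$tx_start), .data$tx_id)
                }
                first(.data$tx_id[o])
              },
              .groups = "drop") %>%
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end - 1))
  fie <- purrr::map2_dbl(genes$gene_id, genes$ref_tx, function(g, t) {
    ex <- exons %>% filter(.data$gene_id == g, .data$tx_id == t)
    strand <- ex$strand[1]
    if (strand == "+") {
      ex <- arrange(ex, .data$start)
      if (nrow(ex) == 1) ex$end[1] else ex$start[2]
    } else {
      ex <- arrange(ex, -.data$start)
      if (nrow(ex) == 1) ex$start[1] - 1 else ex$end[2] - 1
    }
  })
  genes %>%
    mutate(first_intron_end = fie) %>%
    select("gene_id", "chrom", "strand", "start", "end", "tss",
           "first_intron_end", "tx_starts", "tx_ends", "tx3p") %>%
    arrange(.data$chrom, .data$start)
}

#' Read gene models
#'
#' Builds a gene-level table with a strand-aware TSS and the boundary of the
#' first intron of a reference transcript (needed for the TSS-flanking peak
#' category). `first_intron_end` is the transcription-order boundary: on `+`
#' the exclusive end of intron 1 (= start of exon 2), on `-` the inclusive
#' first base of exon 2. Single-exon reference transcripts fall back to the
#' strand-aware end of the first exon, with a warning.
#'
#' @param path File path.
#' @param format `"gff3"`, `"bed12"` or `"tsv"` (the package's own
#'   tab-separated gene table, as written by [write_gene_models()]).
#' @param reference Which transcript defines the first intron:
#'   `"most_5prime"` (default) or `"longest"`.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `first_intron_end` and list-columns `tx_starts`, `tx_ends`,
#'   `tx3p` (strand-aware transcript 3' ends).
#' @export
read_gene_models <- function(path, format = c("gff3", "bed12", "tsv"),
                             reference = c("most_5prime", "longest")) {
  format <- match.arg(format)
  reference <- match.arg(reference)
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric(),
                  tss = numeric(), first_intron_end = numeric(),
                  tx_starts = list(), tx_ends = list(), tx3p = list())
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(x) == 0) return(empty)
    parse_list <- function(s) lapply(strsplit(as.character(s), ";"), as.numeric)
    return(as_tibble(x) %>%
             mutate(tx_starts = parse_list(.data$tx_starts),
                    tx_ends = parse_list(.data$tx_ends),
                    tx3p = parse_list(.data$tx3p)) %>%
             arrange(.data$chrom, .data$start))
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) return(empty)
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    ex <- gr[type == "exon"]
    if (length(ex) == 0) return(empty)
    exmd <- S4Vectors::mcols(ex)
    parent <- as.character(S4Vectors::unstrsplit(exmd$Parent, ","))
    txs <- gr[type %in% c("mRNA", "transcript")]
    txmd <- S4Vectors::mcols(txs)
    tx2gene <- setNames(as.character(S4Vectors::unstrsplit(txmd$Parent, ",")),
                        as.character(txmd$ID))
    exons <- tibble(
      gene_id = unname(tx2gene[parent]),
      tx_id = parent,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1,
      end = as.numeric(GenomicRanges::end(ex))
    )
    return(.genes_from_exons(exons, reference))
  }
  # BED12: one line per transcript, name "gene|tx" (or gene id alone)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty)
  md <- S4Vectors::mcols(gr)
  nm <- as.character(md$name)
  gene_id <- sub("\\|.*$", "", nm)
  tx_id <- ifelse(grepl("\\|", nm), sub("^.*\\|", "", nm),
                  paste0(nm, ".t", seq_along(nm)))
  blocks <- md$blocks
  exons <- purrr::map_dfr(seq_along(gr), function(i) {
    b <- blocks[[i]]
    tibble(
      gene_id = gene_id[i], tx_id = tx_id[i],
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(GenomicRanges::strand(gr[i])),
      start = GenomicRanges::start(gr[i]) - 1 + IRanges::start(b) - 1,
      end = GenomicRanges::start(gr[i]) - 1 + IRanges::end(b)
    )
  })
  exons$strand[!exons$strand %in% c("+", "-")] <- "+"
  .genes_from_exons(exons, reference)
}

#' Write gene models as the package TSV
#'
#' List-columns are serialised as `;`-joined numbers; round-trips through
#' `read_gene_models(format = "tsv")`.
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  fmt <- function(l) vapply(l, function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                                                 collapse = ";"), character(1))
  readr::write_tsv(genes %>%
                     mutate(tx_starts = fmt(.data$tx_starts),
                            tx_ends = fmt(.data$tx_ends),
                            tx3p = fmt(.data$tx3p)),
                   path, progress = FALSE)
  invisible(path)
}

#' Read probe alignment records
#'
#' Tab-separated with header: `probe_id`, `target` (`transcript`/`genome`),
#' `chrom`, `start`, `end`, `mismatches`, `gene_id` (owning gene for
#' transcript hits, `NA` for genomic hits), `within_2kb_3prime`
#' (logical, transcript hits only).
#'
#' @param path File path.
#' @return Tibble of alignment records.
#' @export
read_probe_alignments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "target", "mismatches")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("probe alignment table `%s` missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  as_tibble(x)
}

#' Read an expression table
#'
#' Columns: `probe_id`, `avg_log_intensity`, `fc_sirna`, `fc_ligand`
#' (linear fold changes, > 0; values < 1 encode down-regulation).
#'
#' @param path File path.
#' @return Tibble of expression records.
#' @export
read_expression_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "avg_log_intensity", "fc_sirna", "fc_ligand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("expression table `%s` missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (any(x$fc_sirna <= 0 | x$fc_ligand <= 0, na.rm = TRUE)) {
    abort(sprintf("expression table `%s`: fold changes must be > 0", path))
  }
  as_tibble(x)
}

#' Read a trait-SNP catalog
#'
#' Tab-separated with header: `trait`, `chrom`, `pos` (0-based position).
#' @param path File path.
#' @return Tibble `trait`, `chrom`, `pos`.
#' @export
read_snp_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("trait", "chrom", "pos"), names(x))
  if (length(miss) > 0) {
    abort(sprintf("SNP catalog `%s` missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  as_tibble(x)
}

#' Read chromosome sizes
#'
#' Two tab-separated columns without header: chromosome name, length (bp).
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       show_col_types = FALSE, progress = FALSE)
  setNames(as.numeric(x$size), x$chrom)
}
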