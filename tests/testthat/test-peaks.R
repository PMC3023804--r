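mk_peaks <- function(fdr, control_tags, id = sprintf("p%02d", seq_along(fdr))) {
  tibble::tibble(peak_id = id, chrom = "chr1",
                 start = 1000 * seq_along(fdr),
                 end = 1000 * seq_along(fdr) + 500,
                 summit = 250, tag_count = 100, fold_enrichment = 10,
                 fdr = fdr, control_tags = control_tags)
}

# one + strand and one - strand gene with known structure
mk_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    start = c(100000, 300000), end = c(120000, 320000),
    tss = c(100000, 319999),
    first_intron_end = c(102000, 317999),
    tx_starts = list(100000, 300000), tx_ends = list(120000, 320000),
    tx3p = list(119999, 300000))
}

test_that("high-confidence filtering applies both strict bounds and the exclusion list", {
  cfg <- pipeline_config()
  p <- mk_peaks(fdr = c(0.04, 0.05, 0.01, 0.0499999),
                control_tags = c(99, 10, 100, 0))
  kept <- filter_high_confidence(p, cfg)
  expect_equal(kept$peak_id, c("p01", "p04"))
  cfg2 <- pipeline_config(exclude_peak_ids = "p01")
  expect_equal(filter_high_confidence(p, cfg2)$peak_id, "p04")
  expect_error(filter_high_confidence(mk_peaks(NA, 1), cfg), "FDR")
})

test_that("enlarging the filter bounds never shrinks the retained set", {
  withr::with_seed(21, {
    p <- mk_peaks(fdr = runif(50), control_tags = floor(runif(50, 0, 200)))
    prev <- character(0)
    for (fm in c(0.01, 0.05, 0.2, 1)) {
      for (cm in c(10, 100, 300)) {
        kept <- filter_high_confidence(p, pipeline_config(fdr_max = fm,
                                                          control_tags_max = cm))
        if (fm == 0.01 && cm == 10) prev <- kept$peak_id
      }
    }
    k1 <- filter_high_confidence(p, pipeline_config(fdr_max = 0.02,
                                                    control_tags_max = 50))
    k2 <- filter_high_confidence(p, pipeline_config(fdr_max = 0.1,
                                                    control_tags_max = 150))
    expect_true(all(k1$peak_id %in% k2$peak_id))
  })
})

test_that("peak categorisation follows the window definitions and precedence", {
  genes <- mk_genes()
  cfg <- pipeline_config()
  at <- function(pos) tibble::tibble(peak_id = "x", chrom = "chr1",
                                     start = pos - 100, end = pos + 100,
                                     summit = 100, tag_count = 1,
                                     fold_enrichment = 1, fdr = 0.01,
                                     control_tags = 0)
  categ <- function(pos) as.character(categorize_peaks(at(pos), genes, cfg)$category)
  # 100 bp downstream of the + TSS, inside exon 1
  expect_equal(categ(100100), "tss_flanking")
  # 30 kb upstream of the + gene
  expect_equal(categ(70000), "distant")
  # third-intron-like position: past the first-intron boundary, inside gene
  expect_equal(categ(103500), "intragenic")
  # exactly -5000 of the + TSS is still flanking; -5001 is upstream
  expect_equal(categ(95000), "tss_flanking")
  expect_equal(categ(94999), "upstream")
  # exactly -25000 is upstream, -25001 distant
  expect_equal(categ(75000), "upstream")
  expect_equal(categ(74999), "distant")
  # minus-strand gene: flanking window sits above the boundary
  expect_equal(categ(319000), "tss_flanking")
  expect_equal(categ(324999), "tss_flanking")  # +5000 on - strand
  expect_equal(categ(325000), "upstream")
  expect_equal(categ(310000), "intragenic")
  # anchor gene and signed distance are strand-aware
  res <- categorize_peaks(at(95000), genes, cfg)
  expect_equal(res$anchor_gene_id, "gA")
  expect_equal(res$signed_tss_distance, -5000)
  res2 <- categorize_peaks(at(325000), genes, cfg)
  expect_equal(res2$anchor_gene_id, "gB")
  expect_equal(res2$signed_tss_distance, -5001)
})

test_that("an empty gene list makes every peak distant", {
  p <- mk_peaks(0.01, 0)
  res <- categorize_peaks(p, mk_genes()[0, ], pipeline_config())
  expect_equal(as.character(res$category), "distant")
  expect_true(is.na(res$anchor_gene_id))
})

test_that("category summaries count every peak exactly once", {
  st <- synthesize_study(seed = 3)
  res <- categorize_peaks(st$peaks, st$genes, st$config)
  s <- summarize_categories(res)
  expect_equal(sum(s$n), nrow(st$peaks))
  expect_equal(sum(s$fraction), 1)
  truth_tab <- table(factor(st$truth$peaks$category,
                            levels = levels(s$category)))
  expect_equal(s$n, as.integer(truth_tab))
  expect_warning(s0 <- summarize_categories(res[0, ]), "no peaks")
  expect_equal(sum(s0$n), 0)
  expect_equal(sum(s0$fraction), 0)
})

test_that("H3K4me3 association is inclusive at the window boundary", {
  cfg <- pipeline_config()
  pk <- mk_peaks(0.01, 0)[1, ]  # [1000, 1500)
  h_at <- function(gap) tibble::tibble(peak_id = "h1", chrom = "chr1",
                                       start = 1500 + gap, end = 2000 + gap)
  expect_true(associate_h3k4me3(pk, h_at(150000), cfg)$h3k4_partnered)
  expect_true(associate_h3k4me3(pk, h_at(200000), cfg)$h3k4_partnered)
  expect_false(associate_h3k4me3(pk, h_at(200001), cfg)$h3k4_partnered)
  expect_equal(associate_h3k4me3(pk, h_at(200000), cfg)$h3k4_distance, 200000)
  # window 0 partners exactly overlap or abutment
  cfg0 <- pipeline_config(h3k4_window = 1e-9)
  expect_false(associate_h3k4me3(pk, h_at(1), cfg0)$h3k4_partnered)
  expect_true(associate_h3k4me3(pk, h_at(0), cfg0)$h3k4_partnered)
  ov <- tibble::tibble(peak_id = "h1", chrom = "chr1", start = 1400, end = 1600)
  expect_true(associate_h3k4me3(pk, ov, cfg0)$h3k4_partnered)
  # different chromosome never partners
  far <- tibble::tibble(peak_id = "h1", chrom = "chr9", start = 1500, end = 2000)
  expect_false(associate_h3k4me3(pk, far, cfg)$h3k4_partnered)
})

test_that("Pol II occupancy requires strictly more than the tag bound", {
  cfg <- pipeline_config()
  region <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  tags_n <- function(k) tibble::tibble(chrom = "chr1",
                                       pos = seq(1000, 1999, length.out = k))
  expect_true(polII_occupancy(region, tags_n(51), cfg))
  expect_false(polII_occupancy(region, tags_n(50), cfg))
  expect_false(polII_occupancy(region, tags_n(50)[0, ], cfg))
  # tags at end are outside the half-open region
  edge <- tibble::tibble(chrom = "chr1", pos = c(rep(1500, 50), 2000))
  expect_false(polII_occupancy(region, edge, cfg))
})

test_that("peak-gene links match an all-pairs brute-force window check", {
  withr::with_seed(22, {
    cfg <- pipeline_config(gene_link_window = 5000)
    genes <- mk_genes()
    for (rep in 1:10) {
      start <- floor(runif(10, 0, 400000))
      peaks <- tibble::tibble(peak_id = sprintf("p%02d", 1:10), chrom = "chr1",
                              start = start, end = start + 500)
      links <- link_peaks_to_genes(peaks, genes, cfg)
      for (i in 1:10) {
        for (j in seq_len(nrow(genes))) {
          # independent gap computation from the interval endpoints
          d <- max(0, genes$start[j] - peaks$end[i],
                   peaks$start[i] - genes$end[j])
          linked <- any(links$peak_id == peaks$peak_id[i] &
                          links$gene_id == genes$gene_id[j])
          expect_identical(linked, d <= 5000)
        }
      }
    }
  })
})
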