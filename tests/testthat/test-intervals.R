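test_that("interval distance handles identity, abutment, gaps and chromosomes", {
  iv <- function(chrom, start, end) tibble::tibble(chrom = chrom,
                                                   start = start, end = end)
  expect_equal(interval_distance(iv("chr1", 100, 200), iv("chr1", 100, 200)), 0)
  expect_equal(interval_distance(iv("chr1", 100, 200), iv("chr1", 200, 300)), 0)
  expect_equal(interval_distance(iv("chr1", 100, 200), iv("chr1", 500, 600)), 300)
  expect_equal(interval_distance(iv("chr1", 500, 600), iv("chr1", 100, 200)), 300)
  expect_identical(interval_distance(iv("chr1", 0, 10), iv("chr2", 0, 10)), Inf)
  expect_error(interval_distance(iv("chr1", 200, 100), iv("chr1", 0, 10)),
               "malformed")
})

test_that("distance, overlap and merge agree with per-base oracles", {
  withr::with_seed(11, {
    for (rep in 1:60) {
      a <- random_intervals(1)
      b <- random_intervals(1)
      expect_equal(interval_distance(a, b), bf_distance(a, b))
      expect_equal(overlap_bp(a, b), bf_overlap_bp(a, b))
    }
    for (rep in 1:25) {
      x <- random_intervals(8)
      y <- random_intervals(6)
      gap <- sample(c(0, 1, 5, 50), 1)
      m <- merge_intervals(x, gap = gap)
      o <- bf_merge(x, gap = gap)
      expect_equal(as.data.frame(m), as.data.frame(o), ignore_attr = TRUE)
      expect_equal(overlap_bp(x, y), bf_overlap_bp(x, y))
      expect_equal(overlap_bp(x, y), overlap_bp(y, x))
      expect_equal(total_bp(x), bf_total_bp(x))
    }
  })
})

test_that("merge_intervals is idempotent and separates by more than the gap", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      x <- random_intervals(10)
      m <- merge_intervals(x, gap = 3)
      expect_identical(merge_intervals(m, gap = 3), m)
      by_chrom <- split(m, m$chrom)
      for (mm in by_chrom) {
        if (nrow(mm) > 1) expect_true(all(mm$start[-1] - mm$end[-nrow(mm)] > 3))
      }
    }
  })
})

test_that("zero distance coincides with overlap or abutment", {
  withr::with_seed(13, {
    for (rep in 1:200) {
      a <- random_intervals(1, chroms = "chrA", max_coord = 300, max_width = 40)
      b <- random_intervals(1, chroms = "chrA", max_coord = 300, max_width = 40)
      d <- interval_distance(a, b)
      ov <- overlap_bp(a, b)
      abut <- a$end == b$start || b$end == a$start
      expect_identical(d == 0, ov > 0 || abut)
    }
  })
})

test_that("peak tables round-trip through write and read", {
  withr::with_seed(14, {
    n <- 100
    start <- floor(runif(n, 0, 1e6))
    peaks <- tibble::tibble(
      peak_id = sprintf("pk%03d", 1:n), chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = start, end = start + floor(runif(n, 100, 2000)),
      summit = floor(runif(n, 0, 100)), tag_count = floor(runif(n, 1, 500)),
      fold_enrichment = round(runif(n, 1, 50), 3),
      fdr = round(runif(n), 5), control_tags = floor(runif(n, 0, 200)))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_peak_table(peaks, path)
    back <- read_peak_table(path)
    expect_equal(as.data.frame(back), as.data.frame(peaks))
  })
})

test_that("peak table reader validates columns and coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart", "chr1\t10"), path)
  expect_error(read_peak_table(path), "end")
  writeLines(c("chrom\tstart\tend", "chr1\t100\t50"), path)
  expect_error(read_peak_table(path), "line")
  writeLines(c("chrom\tstart\tend", "chr1\t100\t400"), path)
  ok <- read_peak_table(path)
  expect_equal(nrow(ok), 1)
  # 1-based dialect shifts starts down by one
  one <- read_peak_table(path, coords = "one_based")
  expect_equal(one$start, 99)
  expect_equal(one$end, 400)
})

test_that("gene models compute strand-aware TSS and first-intron boundary", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gplus",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gplus.t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=gplus.t1",
    "chr1\tsrc\tgene\t101\t400\t.\t-\t.\tID=gminus",
    "chr1\tsrc\tmRNA\t101\t400\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr1\tsrc\texon\t101\t200\t.\t-\t.\tParent=gminus.t1",
    "chr1\tsrc\texon\t301\t400\t.\t-\t.\tParent=gminus.t1"), gff)
  g <- read_gene_models(gff, format = "gff3")
  gp <- g[g$gene_id == "gplus", ]
  gm <- g[g$gene_id == "gminus", ]
  expect_equal(gp$tss, 100)
  expect_equal(gp$first_intron_end, 300)
  expect_equal(gm$tss, 399)
  expect_equal(gm$first_intron_end, 199)
})

test_that("single-exon reference transcripts fall back with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1.t1"), gff)
  expect_warning(g <- read_gene_models(gff, format = "gff3"), "single-exon")
  expect_equal(g$first_intron_end, 200)
})

test_that("gene model TSV round-trips including transcript list columns", {
  genes <- generate_genome(n_genes = 12, chrom_sizes = c(chrZ = 1e6), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(genes[setdiff(names(genes), "zone")], path)
  back <- read_gene_models(path, format = "tsv")
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tss, genes$tss)
  expect_equal(back$first_intron_end, genes$first_intron_end)
  expect_equal(back$tx3p, genes$tx3p)
})

test_that("BED12 transcripts group into genes with strand-aware boundaries", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste("chr1", 100, 400, "gA|t1", 0, "+", 100, 400, "0", 2,
          "100,100", "0,200", sep = "\t"),
    paste("chr1", 100, 350, "gA|t2", 0, "+", 100, 350, "0", 2,
          "100,50", "0,200", sep = "\t"),
    paste("chr1", 1000, 1400, "gB|t1", 0, "-", 1000, 1400, "0", 2,
          "100,100", "0,300", sep = "\t")), bed)
  g <- read_gene_models(bed, format = "bed12")
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(g$tss, c(100, 1399))
  expect_equal(g$first_intron_end, c(300, 1099))
  expect_equal(lengths(g$tx3p), c(2L, 1L))
})

test_that("an empty gene file yields an empty model table", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  g <- read_gene_models(gff, format = "gff3")
  expect_equal(nrow(g), 0)
})
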