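test_that("generated genomes are deterministic, non-overlapping and well-formed", {
  g1 <- generate_genome(n_genes = 40, chrom_sizes = c(c1 = 2e6, c2 = 2e6),
                        seed = 8)
  g2 <- generate_genome(n_genes = 40, chrom_sizes = c(c1 = 2e6, c2 = 2e6),
                        seed = 8)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 40)
  # no overlap between gene spans (per-base oracle on scaled coordinates)
  for (cn in unique(g1$chrom)) {
    gg <- g1[g1$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # strand-aware invariants
  expect_true(all(ifelse(g1$strand == "+", g1$tss == g1$start,
                         g1$tss == g1$end - 1)))
  expect_true(all(g1$first_intron_end > g1$start &
                    g1$first_intron_end < g1$end))
  expect_true(all(g1$start >= 0))
  expect_equal(nrow(attr(g1, "tss")), 40)
  g0 <- generate_genome(n_genes = 0, chrom_sizes = c(c1 = 1e5), seed = 1,
                        layout = tibble::tibble(chrom = "c1", lo = 0,
                                                hi = 1e5, n = 0))
  expect_equal(nrow(g0), 0)
  expect_error(generate_genome(n_genes = 50, chrom_sizes = c(c1 = 1e5)),
               "infeasible")
})

test_that("planted peak categories are recovered by the categoriser", {
  genes <- generate_genome(n_genes = 60, chrom_sizes = c(c1 = 3e6), seed = 9)
  out <- generate_peaks(genes, c(c1 = 3e6),
                        quota = c(tss_flanking = 20, intragenic = 10,
                                  upstream = 5, distant = 0),
                        frac_low_quality = 0, seed = 10)
  res <- categorize_peaks(out$peaks, genes)
  m <- merge(out$truth, res[c("peak_id", "category")], by = "peak_id")
  expect_equal(as.character(m$category.y), m$category.x)
  expect_equal(sum(m$category.x == "tss_flanking"), 20)
})

test_that("uniformly low-quality peaks leave the high-confidence set empty", {
  genes <- generate_genome(n_genes = 30, chrom_sizes = c(c1 = 2e6), seed = 12)
  out <- generate_peaks(genes, c(c1 = 2e6),
                        quota = c(tss_flanking = 10, intragenic = 0,
                                  upstream = 0, distant = 0),
                        frac_low_quality = 1, seed = 13)
  expect_equal(nrow(filter_high_confidence(out$peaks)), 0)
  expect_false(any(out$truth$high_confidence))
})

test_that("planted Pol II occupancy matches the designated genes", {
  genes <- generate_genome(n_genes = 30, chrom_sizes = c(c1 = 2e6), seed = 14)
  out <- generate_peaks(genes, c(c1 = 2e6),
                        quota = c(tss_flanking = 5, intragenic = 0,
                                  upstream = 0, distant = 0),
                        polII_positive_fraction = 0.5, seed = 15)
  h3k4 <- out$h3k4
  occ <- polII_occupancy(h3k4[c("chrom", "start", "end")], out$polII_tags)
  gt <- out$gene_truth[match(h3k4$peak_id, out$gene_truth$h3k4_peak_id), ]
  expect_equal(occ, gt$polII_positive)
})

test_that("planted expression responses are recovered exactly at zero noise", {
  genes <- generate_genome(n_genes = 30, chrom_sizes = c(c1 = 2e6), seed = 16)
  targets <- genes$gene_id[1:9]
  out <- generate_expression(genes, targets,
                             response_quota = c(type_I = 3, type_II = 3,
                                                type_III = 3),
                             noise_sd = 0, seed = 17)
  expr <- out$expression
  rep_fc <- expr[match(sprintf("P_%s_1", targets), expr$probe_id), ]
  got <- classify_response(rep_fc$fc_sirna, rep_fc$fc_ligand)
  want <- out$truth$planted_response[match(targets, out$truth$gene_id)]
  expect_equal(as.character(got), want)
  # heavy noise degrades recovery; the rate is reported, not asserted
  noisy <- generate_expression(genes, targets,
                               response_quota = c(type_I = 3, type_II = 3,
                                                  type_III = 3),
                               noise_sd = 1, seed = 17)
  nf <- noisy$expression[match(sprintf("P_%s_1", targets),
                               noisy$expression$probe_id), ]
  rec <- mean(as.character(classify_response(nf$fc_sirna, nf$fc_ligand)) ==
                want)
  expect_true(rec >= 0 && rec <= 1)
})

test_that("generated bundles parse through the package readers unchanged", {
  st <- synthesize_study(seed = 4)
  dir <- withr::local_tempdir()
  write_peak_table(st$peaks, file.path(dir, "peaks.tsv"))
  expect_equal(as.data.frame(read_peak_table(file.path(dir, "peaks.tsv"))),
               as.data.frame(st$peaks))
  write_tag_track(st$polII_tags, file.path(dir, "polII.bed"))
  back <- read_tag_track(file.path(dir, "polII.bed"))
  expect_equal(back$pos, st$polII_tags$pos)
  write_gene_models(st$genes[setdiff(names(st$genes), "zone")],
                    file.path(dir, "genes.tsv"))
  gm <- read_gene_models(file.path(dir, "genes.tsv"), format = "tsv")
  expect_equal(gm$tss, st$genes$tss)
  readr::write_tsv(st$snps, file.path(dir, "snps.tsv"))
  expect_equal(as.data.frame(read_snp_catalog(file.path(dir, "snps.tsv"))),
               as.data.frame(st$snps))
})

test_that("the same seed reproduces the whole bundle", {
  a <- synthesize_study(seed = 6)
  b <- synthesize_study(seed = 6)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$expression, b$expression)
  expect_identical(a$snps, b$snps)
  expect_identical(a$truth$target_genes, b$truth$target_genes)
  c <- synthesize_study(seed = 7)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("a planted SNP catalog at null expectation shows no systematic winner", {
  # planted fraction set to 0: the "planted" trait is itself a null draw
  st <- synthesize_study(seed = 9)
  tr <- st$truth$peaks
  q <- st$peaks[tr$high_confidence & tr$h3k4_partnered, ]
  ranks <- integer(0)
  for (s in 1:5) {
    cat0 <- generate_snp_catalog(q, st$tss, st$chrom_sizes, n_traits = 6,
                                 snps_per_trait = 10, planted_fraction = 0,
                                 seed = 70 + s)
    res <- enrichment_test(q, cat0$snps, st$tss, st$chrom_sizes,
                           n_trials = 150, seed = 170 + s)
    ranks <- c(ranks, which(res$trait == "planted_trait"))
  }
  expect_true(any(ranks > 1))
})
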