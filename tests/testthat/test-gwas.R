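test_that("SNP extension, clipping and merging follow the flank rule", {
  cs <- c(chr1 = 1e6)
  one <- extend_and_merge(tibble::tibble(chrom = "chr1", pos = 500000),
                          flank = 200000, chrom_sizes = cs)
  expect_equal(one$start, 300000)
  expect_equal(one$end, 700001)
  two <- extend_and_merge(tibble::tibble(chrom = "chr1",
                                         pos = c(400000, 500000)),
                          flank = 200000, chrom_sizes = cs)
  expect_equal(nrow(two), 1)
  expect_equal(two$start, 200000)
  expect_equal(two$end, 700001)
  clip <- extend_and_merge(tibble::tibble(chrom = "chr1", pos = 50000),
                           flank = 200000, chrom_sizes = cs)
  expect_equal(clip$start, 0)
  expect_warning(
    skipped <- extend_and_merge(tibble::tibble(chrom = c("chr1", "chrX"),
                                               pos = c(500000, 100)),
                                flank = 1000, chrom_sizes = cs),
    "unknown")
  expect_equal(nrow(skipped), 1)
  # per-trait merging keeps traits separate
  multi <- extend_and_merge(tibble::tibble(trait = c("a", "b"),
                                           chrom = "chr1",
                                           pos = c(500000, 500000)),
                            flank = 1000, chrom_sizes = cs)
  expect_equal(nrow(multi), 2)
})

test_that("the observed statistic is a base-pair percentage of the query", {
  q <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  expect_equal(observed_statistic(q, tibble::tibble(chrom = "chr1",
                                                    start = 0, end = 10)), 100)
  expect_equal(observed_statistic(q, tibble::tibble(chrom = "chr1",
                                                    start = 50, end = 60)), 0)
  expect_equal(observed_statistic(q, tibble::tibble(chrom = "chr1",
                                                    start = 5, end = 20)), 50)
  expect_error(observed_statistic(q[0, ], q), "empty")
})

test_that("null queries conserve interval count, sizes and anchor distances", {
  withr::with_seed(51, {
    cs <- c(chr1 = 2e6, chr2 = 2e6)
    tss <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 20),
                          pos = rep(floor(seq(5e4, 1.9e6, length.out = 20)), 2))
    q <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100000, 700000, 1200000),
                        end = c(100500, 701200, 1200800))
    sizes <- sort(q$end - q$start)
    for (rep in 1:50) {
      s <- sample_null_query(q, tss, cs)
      expect_equal(nrow(s), nrow(q))
      expect_equal(sort(s$end - s$start), sizes)
      expect_true(all(s$start >= 0))
      expect_true(all(s$end <= cs[s$chrom]))
    }
    # a query at distance zero lands overlapping or abutting some TSS
    q0 <- tibble::tibble(chrom = "chr1", start = tss$pos[3] - 100,
                         end = tss$pos[3] + 100)
    for (rep in 1:25) {
      s <- sample_null_query(q0, tss, cs)
      d <- min(interval_distance(
        s[rep(1, nrow(tss)), ],
        tibble::tibble(chrom = tss$chrom, start = tss$pos,
                       end = tss$pos + 1)))
      expect_equal(d, 0)
    }
  })
})

test_that("null anchors are drawn uniformly over the TSS set", {
  withr::with_seed(52, {
    cs <- c(chr1 = 1e6)
    tss <- tibble::tibble(chrom = "chr1", pos = c(200000, 800000))
    q <- tibble::tibble(chrom = "chr1", start = 200000, end = 200400)
    hits1 <- 0
    n <- 1000
    for (i in 1:n) {
      s <- sample_null_query(q, tss, cs)
      if (abs(s$start - 200000) < 1e5) hits1 <- hits1 + 1
    }
    expect_gt(hits1 / n, 0.45)
    expect_lt(hits1 / n, 0.55)
  })
})

test_that("empirical p-values floor at 3/N and tie to 1 when nothing beats zero", {
  cs <- c(chr1 = 1e6)
  tss <- tibble::tibble(chrom = "chr1", pos = floor(seq(5e4, 9.5e5, length.out = 15)))
  q <- tibble::tibble(chrom = "chr1", start = 500000, end = 500500)
  # trait nowhere near anything: observed 0, every trial ties at 0 -> p = 1
  far <- tibble::tibble(trait = "far", chrom = "chr1", pos = 1000)
  expect_warning(
    res <- enrichment_test(q, far, tss, cs, n_trials = 50, flank = 100,
                           seed = 1),
    "null mean")
  expect_equal(res$observed_pct, 0)
  expect_equal(res$p_value, 1)
  # a trait covering the query but (at this seed) never reached by the null
  tss_dense <- tibble::tibble(chrom = "chr1",
                              pos = floor(seq(5e4, 9.5e5, length.out = 200)))
  near <- tibble::tibble(trait = "near", chrom = "chr1", pos = 500250)
  expect_warning(
    res2 <- enrichment_test(q, near, tss_dense, cs, n_trials = 200,
                            flank = 2000, seed = 2),
    "null mean")
  expect_equal(res2$observed_pct, 100)
  expect_equal(res2$p_value, 3 / 200)
  expect_identical(res2$enrichment, Inf)
  # a single exceedance is reported as 1/N: the floor acts only at zero
  res3 <- enrichment_test(q, near, tss_dense, cs, n_trials = 200,
                          flank = 2000, seed = 1)
  expect_equal(res3$p_value, 1 / 200)
})

test_that("enrichment results are reproducible given a seed", {
  st <- synthesize_study(seed = 5)
  q <- st$peaks[1:40, ]
  a <- enrichment_test(q, st$snps, st$tss, st$chrom_sizes, n_trials = 100,
                       seed = 99)
  b <- enrichment_test(q, st$snps, st$tss, st$chrom_sizes, n_trials = 100,
                       seed = 99)
  expect_identical(a, b)
  c <- enrichment_test(q, st$snps, st$tss, st$chrom_sizes, n_trials = 100,
                       seed = 100)
  expect_false(identical(a$null_mean_pct, c$null_mean_pct))
})

test_that("Benjamini-Hochberg agrees with the from-definition oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(1), 1)
  expect_error(benjamini_hochberg(c(0.5, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  withr::with_seed(53, {
    fixed <- c(
      list(c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205),
           c(0.5, 0.5, 0.5), c(0.04, 0.04, 0.9), c(1e-6, 1, 0.5, 0.25)),
      replicate(20, runif(sample(2:12, 1)), simplify = FALSE))
    for (p in fixed) {
      q <- benjamini_hochberg(p)
      expect_equal(q, bf_bh(p))
      expect_true(all(q >= p - 1e-12))
      expect_true(all(q <= 1))
      # q is monotone in p
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-12))
    }
  })
})
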