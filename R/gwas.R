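## Monte Carlo test for enrichment of a peak set near GWAS trait SNPs.
##
## Trait SNPs are extended symmetrically and merged; the observed statistic
## is the percentage of query bases covered by the extended trait set. The
## null model redraws the query while preserving the number of intervals,
## the multiset of interval sizes, and each interval's distance to the
## closest TSS: every interval is re-anchored at a uniformly drawn TSS, on a
## uniformly drawn side, at its original TSS distance. Empirical p-values
## are floored at 3/N when the observed value is never reached, and
## Benjamini-Hochberg correction is applied across traits.

#' Extend SNP positions and merge
#'
#' Every SNP becomes the interval `[pos - flank, pos + flank + 1)`, clipped
#' to its chromosome; overlapping extensions are merged (per trait when a
#' `trait` column is present). SNPs on chromosomes absent from
#' `chrom_sizes` are skipped with a warning.
#'
#' @param snps Tibble `chrom`, `pos` and optionally `trait`.
#' @param flank Extension (bp) on each side; default 200 kb.
#' @param chrom_sizes Named vector of chromosome lengths (for clipping);
#'   `NULL` clips at 0 only.
#' @return Merged interval tibble (with `trait` first when present).
#' @export
extend_and_merge <- function(snps, flank = 200000, chrom_sizes = NULL) {
  stopifnot(flank >= 0)
  snps <- as_tibble(snps)
  if (!is.null(chrom_sizes)) {
    unknown <- !snps$chrom %in% names(chrom_sizes)
    if (any(unknown)) {
      warn(sprintf("%d SNP(s) on unknown chromosomes skipped", sum(unknown)))
      snps <- snps[!unknown, ]
    }
  }
  if (nrow(snps) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
    if ("trait" %in% names(snps)) out <- mutate(out, trait = character(),
                                                .before = 1)
    return(out)
  }
  iv <- snps %>%
    mutate(start = pmax(0, .data$pos - flank),
           end = .data$pos + flank + 1)
  if (!is.null(chrom_sizes)) {
    iv$end <- pmin(iv$end, unname(chrom_sizes[iv$chrom]))
  }
  if ("trait" %in% names(iv)) {
    iv %>%
      group_by(.data$trait) %>%
      dplyr::group_modify(~merge_intervals(.x)) %>%
      ungroup()
  } else {
    merge_intervals(iv)
  }
}

#' Observed overlap statistic
#'
#' Percentage of query base pairs covered by the (extended, merged) trait
#' intervals: `100 * overlap_bp(query, trait) / total_bp(query)`.
#'
#' @param query Query interval tibble (non-empty).
#' @param trait_intervals Interval tibble (one trait's extended intervals).
#' @return A percentage in `[0, 100]`.
#' @export
observed_statistic <- function(query, trait_intervals) {
  tq <- total_bp(query)
  if (tq == 0) abort("query interval set is empty")
  100 * overlap_bp(query, trait_intervals) / tq
}

# Distance from each merged query interval to its closest TSS (point at
# `pos`, occupying [pos, pos+1)): 0 when the TSS is inside or abuts.
.tss_distances <- function(query, tss) {
  d <- rep(Inf, nrow(query))
  for (cn in unique(query$chrom)) {
    pos <- sort(tss$pos[tss$chrom == cn])
    sel <- which(query$chrom == cn)
    if (length(pos) == 0) next
    for (i in sel) {
      s <- query$start[i]; e <- query$end[i]
      j <- findInterval(s, pos)
      cand <- pos[pmax(1, j):pmin(length(pos), j + 2)]
      dd <- ifelse(cand >= s & cand < e, 0,
                   ifelse(cand < s, s - cand - 1, cand - e))
      d[i] <- min(dd)
    }
  }
  if (any(!is.finite(d))) abort("no TSS on some query chromosome")
  d
}

# Vectorised batch sampler: n_total = trials * k placements.
# Returns tibble(trial, chrom, start, end). Off-chromosome draws are
# resampled up to `retries` rounds, then clipped with a warning.
.sample_null_batch <- function(sizes, dists, tss, chrom_sizes, n_trials,
                               retries = 20) {
  k <- length(sizes)
  n <- n_trials * k
  size_v <- rep(sizes, times = n_trials)
  dist_v <- rep(dists, times = n_trials)
  start <- numeric(n); end <- numeric(n); chrom <- character(n)
  todo <- seq_len(n)
  for (r in seq_len(retries)) {
    if (length(todo) == 0) break
    ai <- sample.int(nrow(tss), length(todo), replace = TRUE)
    side <- runif(length(todo)) < 0.5
    pos <- tss$pos[ai]
    # downstream: gap dist between [pos,pos+1) and interval start
    s <- ifelse(side, pos + 1 + dist_v[todo],
                pos - dist_v[todo] - size_v[todo])
    e <- s + size_v[todo]
    cn <- tss$chrom[ai]
    ok <- s >= 0 & e <= unname(chrom_sizes[cn])
    fill <- todo[ok]
    start[fill] <- s[ok]; end[fill] <- e[ok]; chrom[fill] <- cn[ok]
    todo <- todo[!ok]
  }
  if (length(todo) > 0) {
    warn(sprintf("%d null placement(s) clipped to chromosome bounds",
                 length(todo)))
    ai <- sample.int(nrow(tss), length(todo), replace = TRUE)
    cn <- tss$chrom[ai]
    lim <- unname(chrom_sizes[cn])
    s <- pmin(pmax(tss$pos[ai] - size_v[todo] %/% 2, 0),
              pmax(lim - size_v[todo], 0))
    start[todo] <- s; end[todo] <- pmin(s + size_v[todo], lim); chrom[todo] <- cn
  }
  tibble(trial = rep(seq_len(n_trials), each = k),
         chrom = chrom, start = start, end = end)
}

#' Draw one null query
#'
#' Samples a single replicate of the query under the null model: same number
#' of intervals, same sizes, and each interval re-anchored at a uniformly
#' drawn TSS (uniform side) at its original distance to the closest TSS.
#'
#' @param query Query interval tibble (merged internally).
#' @param tss Tibble `chrom`, `pos` of transcription start sites (non-empty).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Interval tibble with as many rows as the merged query.
#' @export
sample_null_query <- function(query, tss, chrom_sizes) {
  if (nrow(tss) == 0) abort("TSS list is empty")
  q <- merge_intervals(query)
  sizes <- q$end - q$start
  dists <- .tss_distances(q, tss)
  .sample_null_batch(sizes, dists, tss, chrom_sizes, 1) %>%
    select("chrom", "start", "end")
}

# Merge intervals within each trial (single pass over the sorted batch).
.merge_by_trial <- function(batch) {
  b <- arrange(batch, .data$trial, .data$chrom, .data$start)
  ck <- match(b$chrom, unique(b$chrom))
  grp_change <- c(TRUE, b$trial[-1] != b$trial[-nrow(b)] |
                    ck[-1] != ck[-nrow(b)])
  key <- cumsum(grp_change)  # dense (trial, chrom) group id
  BIG <- 2^31  # exceeds any chromosome length; key*BIG stays exact in doubles
  run_end <- cummax(b$end + key * BIG) - key * BIG
  new_block <- c(TRUE, b$start[-1] > dplyr::lag(run_end)[-1] |
                   key[-1] != dplyr::lag(key)[-1])
  first_i <- which(new_block)
  last_i <- c(first_i[-1] - 1L, nrow(b))
  tibble(trial = b$trial[first_i], chrom = b$chrom[first_i],
         start = b$start[first_i],
         end = run_end[last_i])
}

#' Monte Carlo enrichment test of a peak set against trait SNP catalogs
#'
#' For each trait, compares the observed percentage base-pair overlap of the
#' query with the trait's extended SNP intervals to its distribution over
#' `n_trials` null queries (see [sample_null_query()]). The empirical
#' p-value counts null statistics `>=` the observed (ties are exceedances);
#' a zero count is assigned the floor `3/n_trials`. Enrichment is the
#' observed statistic divided by the null mean (infinite, with a warning,
#' when the null mean is 0). Benjamini-Hochberg correction is applied
#' across traits.
#'
#' @param query Query peak/interval tibble.
#' @param snps Trait-SNP catalog tibble (`trait`, `chrom`, `pos`).
#' @param tss Tibble `chrom`, `pos` of TSS positions.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_trials Number of Monte Carlo trials (default 10,000).
#' @param flank SNP extension (bp) on each side (default 200 kb).
#' @param seed Optional integer seed; identical seeds give identical
#'   results.
#' @return Tibble of class `chiptarget_enrichment`, sorted by q-value:
#'   `trait`, `observed_pct`, `null_mean_pct`, `enrichment`, `p_value`,
#'   `q_value`, `n_trials`.
#' @export
enrichment_test <- function(query, snps, tss, chrom_sizes,
                            n_trials = 10000, flank = 200000, seed = NULL) {
  if (nrow(tss) == 0) abort("TSS list is empty")
  run <- function() {
    q <- merge_intervals(query)
    if (nrow(q) == 0) abort("query interval set is empty")
    sizes <- q$end - q$start
    dists <- .tss_distances(q, tss)
    traits_iv <- extend_and_merge(snps, flank = flank,
                                  chrom_sizes = chrom_sizes)
    trait_names <- unique(traits_iv$trait)
    batch <- .sample_null_batch(sizes, dists, tss, chrom_sizes, n_trials)
    merged <- .merge_by_trial(batch)
    denom <- rowsum(merged$end - merged$start, merged$trial)[, 1]
    res <- purrr::map_dfr(trait_names, function(tr) {
      ti <- traits_iv %>% filter(.data$trait == tr)
      idx <- .interval_index(ti)
      obs <- 100 * sum(.overlap_with_index(q$chrom, q$start, q$end, idx)) /
        sum(sizes)
      ov <- .overlap_with_index(merged$chrom, merged$start, merged$end, idx)
      null_stats <- 100 * rowsum(ov, merged$trial)[, 1] / denom
      exceed <- sum(null_stats >= obs)
      p <- if (exceed == 0) 3 / n_trials else exceed / n_trials
      nm <- mean(null_stats)
      enr <- if (nm == 0) {
        warn(sprintf("trait `%s`: null mean overlap is 0; enrichment is Inf", tr))
        Inf
      } else obs / nm
      tibble(trait = tr, observed_pct = obs, null_mean_pct = nm,
             enrichment = enr, p_value = p)
    })
    res$q_value <- benjamini_hochberg(res$p_value)
    res$n_trials <- n_trials
    res %>% arrange(.data$q_value, .data$p_value, .data$trait)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("chiptarget_enrichment", class(out))
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate correction:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` on the sorted p-values, capped at
#' 1, returned in input order.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p) | p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
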