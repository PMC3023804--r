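## Genomic interval algebra on tidy tables.
##
## An interval table is any data frame with columns `chrom` (character),
## `start`, `end` (0-based half-open, start < end) and optionally `strand`.
## GenomicRanges/IRanges does the heavy lifting behind this surface.

.validate_intervals <- function(x, arg = "x") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks interval column(s): %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
      abort(sprintf("`%s` has empty chromosome names", arg))
    }
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad) > 0) {
      abort(sprintf(
        "`%s` has malformed interval(s) (need 0 <= start < end) at row(s): %s",
        arg, paste(head(bad, 5), collapse = ", ")))
    }
  }
  x
}

# tibble -> GRanges (internal 0-based half-open -> 1-based closed)
.as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand %in% c("+", "-"), x$strand, "*")
    } else "*"
  )
}

.gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Distance between genomic intervals
#'
#' Gap in base pairs between two intervals under 0-based half-open
#' coordinates: 0 when the intervals overlap or abut, the number of
#' intervening bases otherwise, and `Inf` when the chromosomes differ.
#' Vectorised over rows; `a` and `b` are recycled to a common length.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`.
#' @return Numeric vector of distances (`Inf` across chromosomes).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
#' interval_distance(a, b)  # 300
#' @export
interval_distance <- function(a, b) {
  a <- .validate_intervals(a, "a")
  b <- .validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  d <- pmax(0, a$start[ai] - b$end[bi], b$start[bi] - a$end[ai])
  d[a$chrom[ai] != b$chrom[bi]] <- Inf
  as.numeric(d)
}

#' Merge intervals, bridging gaps up to a given size
#'
#' Collapses an interval set into a disjoint, sorted set. Intervals closer
#' than or exactly `gap` bases apart (including overlapping and abutting
#' intervals) are unioned.
#'
#' @param x Data frame with `chrom`, `start`, `end`.
#' @param gap Non-negative gap (bp) bridged during merging. `gap = 0`
#'   merges overlapping and abutting intervals only.
#' @return Tibble `chrom`, `start`, `end`, sorted by (chrom, start), with
#'   pairwise gaps greater than `gap`.
#' @export
merge_intervals <- function(x, gap = 0) {
  x <- .validate_intervals(x)
  if (gap < 0) abort("`gap` must be >= 0")
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(),
                                  end = numeric()))
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  key <- match(x$chrom, unique(x$chrom))
  BIG <- 2^40  # larger than any coordinate; isolates cummax per chromosome
  run_end <- cummax(x$end + key * BIG) - key * BIG
  new_block <- c(TRUE, x$start[-1] > dplyr::lag(run_end)[-1] + gap |
                   key[-1] != dplyr::lag(key)[-1])
  block <- cumsum(new_block)
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end, block = block) %>%
    group_by(.data$block) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop") %>%
    select("chrom", "start", "end") %>%
    arrange(.data$chrom, .data$start)
  out
}

# Prefix-sum index over a merged, sorted interval set; used for fast
# repeated base-pair overlap queries (Monte Carlo trials).
.interval_index <- function(merged) {
  split(merged[c("start", "end")], merged$chrom) |>
    lapply(function(d) {
      o <- order(d$start)
      s <- d$start[o]; e <- d$end[o]
      list(start = s, end = e, cumw = cumsum(e - s))
    })
}

# Total subject bases covered in [0, x) for each x (vector), one chromosome.
.covered_before <- function(x, idx) {
  i <- findInterval(x, idx$start)
  out <- numeric(length(x))
  pos <- i > 0
  out[pos] <- idx$cumw[i[pos]] - pmax(0, idx$end[i[pos]] - x[pos])
  out
}

# Overlap bp of each query interval with an indexed merged subject set.
.overlap_with_index <- function(chrom, start, end, index) {
  out <- numeric(length(start))
  for (cn in unique(chrom)) {
    idx <- index[[cn]]
    if (is.null(idx)) next
    sel <- chrom == cn
    out[sel] <- .covered_before(end[sel], idx) - .covered_before(start[sel], idx)
  }
  out
}

#' Total base-pair overlap between two interval sets
#'
#' Size of the base-level intersection of the two sets (each merged first, so
#' internal redundancy is not double counted). Symmetric in its arguments.
#'
#' @param query,subject Data frames with `chrom`, `start`, `end`.
#' @return Single non-negative integer-valued number of overlapping bases.
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' s <- tibble::tibble(chrom = "chr1", start = 5, end = 20)
#' overlap_bp(q, s)  # 5
#' @export
overlap_bp <- function(query, subject) {
  q <- merge_intervals(query)
  s <- merge_intervals(subject)
  if (nrow(q) == 0 || nrow(s) == 0) return(0)
  sum(.overlap_with_index(q$chrom, q$start, q$end, .interval_index(s)))
}

#' Total bases covered by an interval set
#'
#' @param x Data frame with `chrom`, `start`, `end`; merged before counting.
#' @return Number of distinct covered bases.
#' @export
total_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Complement of a merged interval set within chromosome bounds.
.interval_complement <- function(x, chrom_sizes) {
  m <- merge_intervals(x)
  out <- lapply(names(chrom_sizes), function(cn) {
    size <- chrom_sizes[[cn]]
    mm <- m[m$chrom == cn, ]
    bounds <- c(0, rbind(mm$start, mm$end), size)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- starts < ends
    tibble(chrom = cn, start = starts[keep], end = ends[keep])
  })
  bind_rows(out)
}

# a \ b on merged sets.
.interval_setdiff <- function(a, b, chrom_sizes) {
  if (nrow(b) == 0) return(merge_intervals(a))
  comp <- .interval_complement(b, chrom_sizes)
  a <- merge_intervals(a)
  if (nrow(a) == 0) return(a)
  gr_a <- .as_gr(a); gr_c <- .as_gr(comp)
  .gr_to_tbl(GenomicRanges::intersect(gr_a, gr_c, ignore.strand = TRUE)) %>%
    arrange(.data$chrom, .data$start)
}

# Uniformly sample n positions from an interval set (base-resolution).
.sample_positions <- function(x, n) {
  m <- merge_intervals(x)
  w <- m$end - m$start
  if (nrow(m) == 0 || sum(w) == 0) abort("cannot sample from an empty region")
  i <- sample.int(nrow(m), n, replace = TRUE, prob = w / sum(w))
  floor(m$start[i] + runif(n) * w[i])
}
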