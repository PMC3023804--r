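# Independent brute-force oracles: everything here works per base / per
# offset on small coordinates, deliberately sharing no code with the
# package internals.

# set of covered bases (0-based positions) of an interval table
bf_bases <- function(x) {
  if (nrow(x) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(x)), function(i) {
    if (x$end[i] <= x$start[i]) return(character(0))
    paste0(x$chrom[i], ":", seq(x$start[i], x$end[i] - 1))
  }))
}

bf_overlap_bp <- function(a, b) {
  length(intersect(unique(bf_bases(a)), unique(bf_bases(b))))
}

bf_total_bp <- function(x) length(unique(bf_bases(x)))

bf_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  ba <- a$start:(a$end - 1)
  bb <- b$start:(b$end - 1)
  d <- min(abs(outer(ba, bb, "-")))
  max(0, d - 1)
}

# merge by painting bases, bridging gaps <= gap
bf_merge <- function(x, gap = 0) {
  out <- list()
  for (cn in sort(unique(x$chrom))) {
    xx <- x[x$chrom == cn, ]
    covered <- sort(unique(unlist(
      lapply(seq_len(nrow(xx)), function(i) xx$start[i]:(xx$end[i] - 1)))))
    runs <- split(covered, cumsum(c(1, diff(covered) > gap + 1)))
    for (r in runs) {
      out[[length(out) + 1]] <- data.frame(chrom = cn, start = min(r),
                                           end = max(r) + 1)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_coord = 9000,
                             max_width = 400) {
  start <- floor(runif(n, 0, max_coord - max_width))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + floor(runif(n, 1, max_width)))
}

# from-definition BH oracle: q_i = min over j with p_j >= p_i of m*p_j/rank_j
bf_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# per-offset, per-strand PPRE oracle sharing nothing with the scanner
bf_iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T", "N"))

bf_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

bf_scan <- function(sequence, pattern, max_core = 2, max_ext = 2) {
  pat <- strsplit(pattern, "")[[1]]
  scan_one <- function(seq_chars, strand, n) {
    res <- list()
    for (off in 0:(length(seq_chars) - 17)) {
      win <- seq_chars[(off + 1):(off + 17)]
      mm <- vapply(1:17, function(j) !win[j] %in% bf_iupac[[pat[j]]],
                   logical(1))
      ext <- sum(mm[1:4]); h1 <- sum(mm[5:10]); sp <- sum(mm[11])
      h2 <- sum(mm[12:17]); core <- h1 + sp + h2
      cls <- if (core == 0 && ext == 0) "dr1_with_extension"
             else if (core == 0) "dr1_only"
             else if ((h1 == 0) != (h2 == 0)) "half_site"
             else "none"
      keep <- (core <= max_core && ext <= max_ext) || cls == "half_site"
      if (keep) {
        pos <- if (strand == "+") off else n - 17 - off
        res[[length(res) + 1]] <- data.frame(
          position = pos, strand = strand, mm_extension = ext,
          mm_core = core, mm_hex1 = h1, mm_hex2 = h2,
          structural_class = cls, stringsAsFactors = FALSE)
      }
    }
    res
  }
  chars <- strsplit(sequence, "")[[1]]
  rc <- strsplit(bf_revcomp(sequence), "")[[1]]
  out <- do.call(rbind, c(scan_one(chars, "+", length(chars)),
                          scan_one(rc, "-", length(chars))))
  if (is.null(out)) {
    out <- data.frame(position = integer(), strand = character(),
                      mm_extension = integer(), mm_core = integer(),
                      mm_hex1 = integer(), mm_hex2 = integer(),
                      structural_class = character())
  }
  out[order(out$mm_extension + out$mm_core, out$position, out$strand), ,
      drop = FALSE]
}
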