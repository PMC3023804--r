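## Consensus PPRE scanning and structural classification.
##
## The consensus is a 17-symbol IUPAC string: a 4-bp 5' extension, the
## DR1 core (hexamer half-site, 1-bp spacer, hexamer half-site). Matches
## are scored per segment so a hit can be classified structurally:
## perfect DR1 with perfect extension, DR1-only, or an extended half-site
## (exactly one perfect hexamer).

.IUPAC_SETS <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) strsplit(s, "")[[1]])
})

#' Define a PPRE consensus
#'
#' The default pattern is the canonical DR1 (`AGGTCA` + 1-bp spacer +
#' `AGGTCA`) with a fully degenerate 4-symbol 5' extension placeholder;
#' supply the experimentally derived 17-mer to use a specific consensus.
#' A sequence base matches a pattern symbol when it belongs to the symbol's
#' IUPAC base set; an `N` in the scanned sequence matches only a pattern
#' `N`.
#'
#' @param pattern 17-symbol IUPAC string (4 extension + 6 + 1 + 6 core).
#' @param max_mismatches_core Reporting budget for the 13-bp DR1 core.
#' @param max_mismatches_extension Reporting budget for the 4-bp extension.
#' @return Object of class `ppre_consensus`.
#' @export
ppre_consensus <- function(pattern = "NNNNAGGTCANAGGTCA",
                           max_mismatches_core = 2,
                           max_mismatches_extension = 2) {
  pattern <- toupper(pattern)
  sym <- strsplit(pattern, "")[[1]]
  if (length(sym) != 17) abort("PPRE consensus must be 17 symbols long")
  bad <- which(!sym %in% names(.IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC symbol at position %d: '%s'",
                  bad[1], sym[bad[1]]))
  }
  structure(list(pattern = pattern, symbols = sym,
                 extension = 1:4, hex1 = 5:10, spacer = 11, hex2 = 12:17,
                 max_mismatches_core = max_mismatches_core,
                 max_mismatches_extension = max_mismatches_extension),
            class = "ppre_consensus")
}

# Per-offset, per-segment mismatch counts on the forward orientation of
# `chars` (character vector of sequence bases).
.segment_mismatches <- function(chars, consensus) {
  L <- 17L
  n <- length(chars)
  n_off <- n - L + 1L
  if (n_off < 1) {
    return(tibble(position = integer(), mm_ext = integer(),
                  mm_hex1 = integer(), mm_spacer = integer(),
                  mm_hex2 = integer()))
  }
  mism <- matrix(0L, nrow = n_off, ncol = L)
  for (j in seq_len(L)) {
    sym <- consensus$symbols[j]
    window <- chars[j:(j + n_off - 1L)]
    ok <- if (sym == "N") window %in% c("A", "C", "G", "T", "N")
          else window %in% .IUPAC_SETS[[sym]]
    mism[, j] <- as.integer(!ok)
  }
  tibble(position = 0:(n_off - 1L),
         mm_ext = as.integer(rowSums(mism[, consensus$extension, drop = FALSE])),
         mm_hex1 = as.integer(rowSums(mism[, consensus$hex1, drop = FALSE])),
         mm_spacer = as.integer(mism[, consensus$spacer]),
         mm_hex2 = as.integer(rowSums(mism[, consensus$hex2, drop = FALSE])))
}

#' Classify a PPRE match structurally
#'
#' * `dr1_with_extension`: DR1 core and 5' extension both perfect;
#' * `dr1_only`: core perfect, extension imperfect;
#' * `half_site`: exactly one perfect hexamer half-site;
#' * `none`: anything else.
#'
#' @param mm_ext,mm_hex1,mm_spacer,mm_hex2 Segment mismatch counts
#'   (vectorised).
#' @return Factor of structural classes.
#' @export
classify_ppre_match <- function(mm_ext, mm_hex1, mm_spacer, mm_hex2) {
  core <- mm_hex1 + mm_spacer + mm_hex2
  out <- rep("none", length(mm_ext))
  out[(mm_hex1 == 0) != (mm_hex2 == 0)] <- "half_site"
  out[core == 0 & mm_ext > 0] <- "dr1_only"
  out[core == 0 & mm_ext == 0] <- "dr1_with_extension"
  factor(out, levels = c("dr1_with_extension", "dr1_only", "half_site", "none"))
}

#' Scan a sequence for PPRE consensus matches
#'
#' Scores every offset on both strands by segment-wise IUPAC mismatch
#' counts. An offset is reported when the core and extension mismatches are
#' within the consensus budgets, or when it is a structural half-site
#' (one perfect hexamer, regardless of the other). Reverse-strand hits are
#' reported at forward 0-based coordinates of the 17-mer's leftmost base.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param consensus A [ppre_consensus()].
#' @return Tibble sorted by (total mismatches, position): `position`,
#'   `strand`, `mm_extension`, `mm_core`, `mm_hex1`, `mm_hex2`,
#'   `structural_class`.
#' @export
scan_ppre <- function(sequence, consensus = ppre_consensus()) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    abort(sprintf("invalid nucleotide '%s' at offset %d", chars[bad[1]],
                  bad[1] - 1L))
  }
  n <- length(chars)
  fwd <- .segment_mismatches(chars, consensus) %>% mutate(strand = "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  rev <- .segment_mismatches(strsplit(rc, "")[[1]], consensus) %>%
    mutate(position = n - 17L - .data$position, strand = "-")
  hits <- bind_rows(fwd, rev) %>%
    mutate(mm_core = .data$mm_hex1 + .data$mm_spacer + .data$mm_hex2,
           structural_class = classify_ppre_match(.data$mm_ext, .data$mm_hex1,
                                                  .data$mm_spacer, .data$mm_hex2),
           total_mm = .data$mm_ext + .data$mm_core) %>%
    filter((.data$mm_core <= consensus$max_mismatches_core &
              .data$mm_ext <= consensus$max_mismatches_extension) |
             .data$structural_class == "half_site") %>%
    arrange(.data$total_mm, .data$position, .data$strand) %>%
    select(position = "position", strand = "strand",
           mm_extension = "mm_ext", mm_core = "mm_core",
           mm_hex1 = "mm_hex1", mm_hex2 = "mm_hex2",
           structural_class = "structural_class")
  hits
}
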