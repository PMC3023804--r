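---
title: "Defining transcription-factor target genes from ChIP-Seq and perturbation profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining transcription-factor target genes from ChIP-Seq and perturbation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiptarget)
library(dplyr)
```

## The problem and the model

A transcription factor ChIP-Seq experiment reports thousands of binding
peaks, but binding does not imply regulation. `chiptarget` encodes a
conservative integrative definition of direct target genes for a nuclear
receptor assayed under two complementary perturbations — depletion of the
receptor by siRNA and activation by a synthetic agonist. The reasoning is
that a *bona fide* target should (a) carry a reproducible, high-quality
binding site, (b) sit in chromatin that is transcriptionally competent
(an H3K4me3-marked, polymerase-loaded promoter nearby), and (c) actually
respond when the receptor is removed or activated.

The cascade, applied in order:

1. **High-confidence peaks.** A peak survives when its peak-caller FDR is
   *strictly* below 0.05 and it holds *strictly* fewer than 100 tags in
   the matched IgG control track. Known-artefact peaks can be removed via
   an explicit `exclude_peak_ids` list; the package never infers such
   removals (in the original analysis they came from visual inspection).
2. **Promoter context.** A peak is kept when the nearest H3K4me3 peak is
   at most 200 kb away (edge-to-edge, inclusive). RNA polymerase II
   occupancy of the partner promoter region — more than 50 tag 5' ends in
   the region, strict — is annotated but does not filter, matching the
   original cascade in which the 414 partnered peaks all proceeded to the
   expression join.
3. **Expression correlation.** Peaks are linked to every gene whose span
   lies within 200 kb (inclusive). A linked gene enters the target set
   when its representative probe — the most strongly regulated
   intensity-passing probe — shows a knockdown fold change ≥ 1.5 or a
   ligand fold change ≥ 1.2 (both inclusive; intensity gate ≥ 6 on the
   averaged log scale, inclusive).

Response modes partition the positive fold-change quadrant: **type I**
(knockdown ≥ 1.5, ligand < 1.2), **type II** (knockdown ≥ 1.5, ligand
≥ 1.2), **type III** (knockdown ≤ 1/1.5; the ligand axis is deliberately
unconstrained because "no response or weak induction" is not quantified —
a `type3_ligand_cap` config option can impose a cap), plus an added
`ligand_only` label so ligand-responsive genes without a knockdown
response remain representable, and `unclassified` for the rest.
Down-regulation is always the reciprocal of the up-threshold (fc ≤ 1/t),
the standard convention for fold changes reported as magnitudes.

## Coordinates and interval conventions

All internal coordinates are 0-based half-open (BED convention); GFF3 and
1-based peak-table dialects are converted at the I/O boundary. Distance
between intervals is the gap: overlapping or abutting intervals are at
distance 0, and every "within D kb" predicate is inclusive (≤ D).
Distances across chromosomes are infinite, never a large number, so
nearest-neighbour logic cannot silently cross chromosomes. Whether the
200-kb H3K4me3 criterion is measured edge-to-edge or summit-to-summit is
not decidable from the published description; this package measures
**edge-to-edge**, which is the more inclusive reading — analyses
reproducing peak counts should be aware of the choice.

Peak location categories use the anchor point (summit when present, else
the interval midpoint) with precedence *TSS-flanking* > *intragenic* >
*upstream* > *distant*. TSS-flanking spans from 5 kb upstream of a TSS to
the 3' end of the first intron of the reference transcript — the
transcript with the most 5' TSS (configurable to the longest transcript;
the source analysis does not state which transcript defines "first
intron"). On the minus strand the boundary is stored as the first base of
exon 2 in transcription order, the exact mirror of the plus-strand
convention; single-exon transcripts fall back to the strand-aware end of
the first exon, with a warning. Ties between equidistant anchor genes are
broken lexicographically for determinism.

## The probe-assignment cascade

Microarray probes are mapped to genes by a 16-rule priority cascade over
their transcriptome and genome alignments. Perfect alignments
(0 mismatches) are consumed by rules 1–8; mismatched alignments only by
the mirrored rules 9–16, so a probe with any perfect evidence is decided
entirely by it. Two readings had to be fixed where the original rule list
is ambiguous: a genomic location covered by several overlapping genes
(rules 5/13) assigns *all* covering genes, and "multiple matches to
transcripts of different genes" (rules 6/14) assigns *no* gene but
records the candidates. Rule 6 also fires when multi-gene transcript
evidence cannot be resolved and no genomic hit lies inside a gene, even
if no genomic record is present at all — the rule text presumes one
exists. "Within 2 kb" of a gene or of a transcript 3' end is inclusive
edge distance. Genes with several intensity-passing probes are
represented by the most strongly regulated one
(max of |log2 fc| over both conditions), ties broken by higher intensity,
then probe id.

## The Monte Carlo enrichment test

To ask whether a peak set is unusually close to GWAS SNPs of a trait,
each SNP is extended by 200 kb on each side, extensions are merged per
trait, and the observed statistic is the percentage of query base pairs
covered. The null model redraws the query while conserving three
properties — the number of intervals, the multiset of their sizes, and
each interval's distance to the closest TSS — by re-anchoring every
interval at a uniformly drawn TSS on a uniformly drawn side (the side is
unstated in the original description; uniform is the symmetric choice).
The anchor is not guaranteed to remain the *closest* TSS after placement;
that approximation is inherent to the scheme and only anchor-distance
preservation is asserted. Placements falling off a chromosome are redrawn
a bounded number of times, then clipped with a warning.

The empirical p-value counts null statistics ≥ the observed (ties are
exceedances — the conservative direction); a zero count is assigned the
floor 3/N, and non-zero counts report count/N unchanged, so values of
1/N or 2/N can occur. Enrichment is observed over null mean (an infinite
sentinel with a warning when the null mean is zero). Benjamini–Hochberg
correction is applied across traits via `stats::p.adjust`; the test suite
checks it against an independent from-definition oracle. A fixed trial
count is used; with the default 10,000 trials the floor is 3 × 10⁻⁴.
Calibration is a tested property: when the query itself is drawn from the
null model, p-values over 200 replicate queries pass a Kolmogorov–Smirnov
uniformity check.

## PPRE scanning

The binding-site consensus is a 17-symbol IUPAC string: a 4-bp 5'
extension followed by a DR1 core (AGGTCA-like hexamer, 1-bp spacer,
second hexamer). The scanner scores every offset on both strands with
*per-segment* mismatch counts, which standard pattern matchers do not
expose; hits are reported when core and extension mismatches are within
the configured budgets (defaults 2 and 2 — configuration values, not
field-calibrated constants) or when the hit is a structural half-site.
Classification is purely structural: perfect core + perfect extension,
perfect core only (DR1-only), exactly one perfect hexamer (extended
half-site), else none. The shipped default pattern is the canonical DR1
with a fully degenerate extension placeholder; the experimentally derived
consensus letters must be supplied by the user, since they come from a
figure, not machine-readable text. A base `N` in the scanned sequence
matches only a pattern `N`.

## What the synthetic generator emulates — and what it does not

`synthesize_study()` builds a two-chromosome, 5-Mb-each toy genome with
200 non-overlapping three-exon genes, chosen so that 200-kb windows
behave non-trivially while per-base oracles remain affordable. Spatial
zones make the planted truth hold *by construction* rather than by
running the pipeline on itself:

* active zones hold the ChIP peaks and H3K4me3 promoter peaks;
* gene-free deserts inside active zones host the *distant* peaks
  (> 25 kb from every TSS, yet within partnering range of a promoter);
* a peak-free zone on chr1 holds regulated decoy genes, more than 200 kb
  from any peak, which must therefore stay out of the target set;
* an inactive zone on chr2 holds promoters without H3K4me3, more than
  200 kb from any active promoter — its peaks are the planted
  unpartnered fraction.

The paperlike preset plants 300 peaks at the published category mix
(49/19/10/22% TSS-flanking/intragenic/upstream/distant), ~80%
high-confidence, ~94% of high-confidence peaks promoter-partnered, 70% of
active genes Pol II positive (51–119 planted tags versus ≤ 50), and 53
target genes at the published validated-set response split of 25/14/14
(type I/II/III), with fold changes drawn clear of the thresholds
(e.g. knockdown 1.8–3.2 for up-regulation) so zero-noise recovery is
exact. The SNP catalog holds 10 traits of 30 SNPs; the planted trait's
SNPs fall within 150 kb of real peaks, the nine null traits are placed by
the package's own null sampler and are therefore honest null draws.
Multiplicative log2 noise (`noise_sd`) degrades fold changes; recovery
under noise is reported by the tests, not asserted.

What passing these tests shows: the implementation applies its stated
rules exactly, end to end, and the Monte Carlo machinery is calibrated.
What it does not show: behaviour on real data — the toy genome has no
overlapping genes (except in dedicated probe fixtures), no unmappable or
repetitive regions, no correlated noise between probes of a gene, ideal
MACS statistics, and far denser gene spacing relative to the 200-kb
windows than the human genome. Published headline counts from the
original biological data are not recomputable at this scale.

## Numerical and design choices

* Interval merging and overlap run on prefix-sum indexes; Monte Carlo
  trials are generated and merged in a single vectorised batch, so a
  10,000-trial test over hundreds of peaks takes seconds.
* Determinism: a single seed drives each generator and
  `enrichment_test()`; identical seeds give bit-identical results
  (tested). No global RNG state leaks (`withr::with_seed`).
* Problem sizes in the test suite — 300 peaks, 200 genes, 500-trial
  calibration with 200 replicates, 20 discrimination replicates — were
  chosen to exercise every code path at comfortable desk scale.
* Degenerate inputs: empty peak sets, empty gene lists, probes without
  alignments, traits with zero null overlap and single-exon transcripts
  all have defined, tested behaviour (empty results, `distant`,
  rule 16 + unaligned flag, infinite enrichment with warning, and the
  documented fallback, respectively).

## Known limitations

* The H3K4me3 "cluster" is operationalised as a single peak; an optional
  pre-merge (`h3k4_merge_gap`) can approximate clustering but is off by
  default.
* The null model's anchor-distance preservation is an approximation of
  "distance to the closest TSS" (see above).
* The probe cascade's ambiguous rules follow one documented reading;
  analyses depending on rules 5/6/13/14 should review those choices.
* Expression calling uses fold-change thresholds, not statistical tests —
  faithful to the original design, but without error control at the
  probe level.
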