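---
title: "Detecting and assembling nuclear mitochondrial sequences with numtsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and assembling nuclear mitochondrial sequences with numtsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtsr)
```

## The problem

NumtS (nuclear mitochondrial sequences) are fragments of mtDNA that have
integrated into nuclear chromosomes, most plausibly during double-strand
break repair. A NumtS catalogue is built by local alignment of the
mitochondrial reference against every nuclear chromosome and a careful
merging of the resulting hits, because a single insertion event is
frequently reported as several high-scoring pairs (HSPs): alignments break
at accumulated substitutions and indels, at intervening repeat insertions,
and — an artifact of linearizing a circular genome — at the control-region
junction, where the D-loop is annotated as the end of the sequence
(positions 16024–16569 in rCRS numbering) followed by its start (1–576).
`numtsr` implements this recipe end to end, together with the summary
statistics, browser tracks and a simulation harness for validating the
pipeline against a known ground truth.

## Detection model

The aligner is a classic seed-and-extend local aligner:

* exact k-mer seeds (default `word_size = 11`, the BLASTN default), with
  highly repetitive seeds (> 60 query occurrences) skipped, and per-diagonal
  thinning of redundant seeds;
* seeds are clustered by diagonal (±64) and subject proximity (≤ 3 kb),
  so one cluster normally corresponds to one insertion;
* each cluster is pre-screened by a cheap ungapped X-drop extension; weak
  isolated seeds — which cannot reach the score threshold and in random
  sequence essentially never do — are dropped, and the rest undergo banded
  affine-gap local dynamic programming (band = seed diagonals ± `band_pad`
  (150), extension margin 1000 bp beyond the outermost seeds, or 64 bp for
  weak short clusters that the band already covers).

Scoring is the BLASTN-style scheme used for the human catalogue: match +2,
mismatch −3, gap open −5, gap extend −2 (a gap of length *g* costs
5 + 2*g*), with `N` scoring as a mismatch and never seeding. Significance
filtering uses a raw-score cutoff `min_raw_score = 62`. Under the
Karlin–Altschul approximation with λ solved from the ungapped stationarity
condition for this scheme on uniform base composition (λ ≈ 0.6343,
K ≈ 0.41), 62 corresponds to E ≈ 10⁻³ for a mitochondrial-genome ×
mammalian-genome search space; the λ and K constants are exposed in
`scoring_scheme()` for users who want the reported approximate E-values on
a different footing. Externally computed BLAST tabular files are filtered
on their own E-value column (`< 1e-3`) instead.

The minus strand is searched against the reverse complement of the
chromosome and mapped back, so every HSP stores its nuclear interval on
the chromosome forward strand (start < end) and its mitochondrial interval
on the mitochondrial plus strand, with a separate strand flag; all
interval arithmetic downstream is strand-agnostic. Internally every
coordinate is 0-based half-open; BLAST tabular (1-based inclusive) and BED
(0-based half-open) conventions are converted only at parse/write
boundaries.

In the test suite the aligner is held to an independent oracle: full
Smith–Waterman with affine gaps (`Biostrings::pairwiseAlignment`) run on
implant neighbourhoods must reproduce the raw score exactly and the
coordinates to within 5 bp, across 0–20 % divergence.

## Assembly rules

Two HSPs on the same chromosome merge when

1. they point in the same direction,
2. the nuclear gap `start₂ − end₁` is **less than** 2,000 bp (strict
   bound; negative gaps, i.e. overlapping HSPs, always pass — overlaps as
   small as −8 bp occur among genuine concatenated fragments), and
3. the oriented mitochondrial gap is **not more than** 2,000 bp
   (inclusive bound). On the plus strand the gap runs from the first
   HSP's mitochondrial end to the second's start; on the minus strand the
   other way, because successive nuclear blocks descend along the
   mitochondrial coordinate. The gap is taken as
   `min(linear, linear mod L)` on the circular reference, which is what
   lets D-loop-junction-spanning chains merge with a circular gap of 0
   and generalizes the device to any circular reference without
   special-casing the junction positions.

The asymmetric bounds (strict nuclear, inclusive mitochondrial) follow the
protocol wording literally and are configurable in `assembly_params()`.
One literal consequence we keep: a nuclear-ordered pair whose
mitochondrial fragments appear in the opposite order has a negative linear
gap and therefore passes the mitochondrial test; merging such pairs is
still gated by nuclear proximity and shared orientation.

Chains are the connected components (transitive closure) of this pairwise
relation within each (chromosome, strand) group — not merely consecutive
neighbours — so chains interrupted by long repetitive insertions still
join whenever any two members satisfy the rule, which is how multi-block
NumtS with up to ten constituent HSPs arise. An optional per-chain
nuclear-extent cap (`max_chain_span`, default none) is available for
sensitivity analysis. The test suite checks the implementation against an
independent graph-components oracle (igraph) on 100+ random instances.

Each assembled NumtS reports its nuclear envelope, a circular
mitochondrial span (computed as the complement of the largest uncovered
circular gap, flagged `wraps_junction` when it crosses the origin), and an
`aggregate_identity` — the alignment-length-weighted mean of member
identities, a derived roll-up chosen as the least surprising summary since
per-HSP identity is the primary quantity. Ids follow the
`HSA_NumtS_xxx` convention (three digits, widening past 999) with `_bN`
suffixes for blocks of multi-member NumtS in nuclear order.

## Statistics

* **Coverage**: `coverage_profile()` counts, per mitochondrial position,
  the HSPs covering it; exported as bedGraph. Conservation (total counts =
  total interval length) is asserted against a brute-force per-position
  oracle.
* **Per-chromosome table**: counts, summed spans and span percentages
  rounded half-away-from-zero to 3 decimals (the spreadsheet convention
  that reproduces published per-chromosome percentages exactly). Because
  it is unstated whether published spans sum outer envelopes or member
  lengths, both modes are provided (`span_mode`); the envelope is the
  default.
* **Quartiles**: `five_number_summary()` uses linear interpolation of
  order statistics with index `(n−1)q` (`stats::quantile` type 7, the
  common spreadsheet default — the convention most likely behind published
  five-number tables); the type is configurable.
* **Correlation**: `pearson_r()` is implemented from the definition and
  cross-checked against `stats::cor` in tests. On the published
  per-chromosome table, NumtS count vs chromosome length gives r = 0.82.
  The companion gene-density correlation is supported only when the user
  supplies a density table, since per-chromosome gene densities are not
  part of the shipped inputs.
* **Flanks**: `flank_repeat_content()` measures the fraction of the 1-kb
  flanks covered by a user-supplied repeat BED (union coverage via
  IRanges), with a cumulative distribution at 1 % bins.

## The simulator and what it does (not) show

`simulate_genome()` implants mutated mitochondrial fragments into an
i.i.d. uniform ACGT background:

* fragment lengths uniform on [31, 15000] bp and target identities
  uniform on [63, 100] % — the ranges observed across the reference human
  catalogue; a range with no stated distribution is sampled uniformly;
* substitutions i.i.d. per base; indel events at 0.001/bp (insertion or
  deletion equally likely, lengths 1 + Geometric(0.7), so single-base
  events dominate) — a rate that keeps alignments contiguous at the
  fragment scale, as observed for real NumtS;
* strand flips with probability 0.5 (no known strand bias), splits into
  2–4 blocks with sub-2-kb spacers with probability 0.2, and
  junction-spanning fragments with probability 0.05 (the D-loop region is
  under-represented among real NumtS, so junction crossers are rare);
* implants are placed ≥ 2.5 kb apart so that distinct events cannot merge
  during assembly, and the truth table records realized identity from the
  mutation log — never from re-alignment — so ground truth is independent
  of the aligner under test.

The background is deliberately repeat-free: it makes recovery metrics
sharp (any false positive is an aligner artifact, not a repeat
confusion). Real flanks are repeat-rich — about 97 % of catalogued NumtS
sit near repeated elements — so passing recovery here demonstrates the
correctness of detection and merge logic, not robustness to segmental
duplications or repeat-mediated ambiguity. Calibration, asserted in the
tests: with 20 implants per genome and default settings, recall and
precision are ≥ 0.95 at identities ≥ 80 %, and junction-spanning implants
assemble into a single NumtS in all seeded cases. Below ~70 % identity,
short fragments legitimately fall under the score threshold, mirroring
the detection limit of the underlying search.

## Tracks and liftover

The four browser tracks are plain BED with UCSC `track` headers: HSPs on
the nucleus (BED6, shading = identity × 10 on the 0–1000 score scale,
not rescaled to the observed identity range, so shading is comparable
across datasets; a bit-score mode exists because "similarity score" is
ambiguous), assembled NumtS (BED6), HSPs on the mitochondrion (BED6), and
the same colored by source chromosome (BED9, itemRgb from an editable
color table following the UCSC chromosome-color convention). Reciprocal
browser hyperlinks have no flat-file equivalent, so nuclear and
mitochondrial items share member ids and a crosslink TSV carries both
locus strings. Junction-wrapping NumtS are drawn as their member HSPs,
which individually never wrap.

Liftover between two mitochondrial references builds a block map from a
banded global alignment under the same scoring scheme (refused below 90 %
identity — such inputs are not homologous references — or above a 100-kb
combined-length cap). Interval endpoints are lifted independently;
endpoints falling in alignment gaps snap *outward*, never truncating an
annotated feature, and are flagged; intervals wholly inside a deletion
are unmapped. The map is always computed from the two supplied sequences
rather than from any hard-coded indel positions. A column-walk oracle
(the exact per-position correspondence of constructed insertion pairs)
pins the implementation in tests.

## Numerical and design choices

* Ambiguity codes other than `N` are rejected at read time (maskable),
  since scoring is defined only on `{A,C,G,T,N}`.
* Word size 11 and no low-complexity filtering are defaults chosen for
  the internal aligner, not inferred from any published run; both matter
  mainly below ~70 % identity.
* Overlapping HSP candidates are de-duplicated keeping the highest score,
  ties broken by leftmost nuclear start — deterministic output.
* All outputs are sorted by karyotype order (1..22, X, Y, then others
  lexicographically) and nuclear start; assembly is invariant to input
  order (asserted by permutation tests).
* Problem sizes in the shipped tests — 16.6-kb reference, 0.15–1-Mb
  simulated chromosomes, 20–30 implants, 100 random assembly instances —
  were chosen so the whole suite exercises every code path in a few
  minutes on one core; all generators are seeded.
* No real mitochondrial sequence ships with the package:
  `synthetic_mito_genome()` provides a seeded random 16,569-bp stand-in,
  clearly labelled synthetic. Analyses of real genomes should supply rCRS
  (NC_012920) or an equivalent reference as FASTA.

## Known limitations

* The aligner reports one HSP per seed cluster (the best local alignment
  there); secondary sub-optimal alignments within the same neighbourhood
  are not reported. BLAST output fed through the tabular path does not
  have this restriction.
* Approximate E-values use ungapped Karlin–Altschul constants; the
  primary filter is the raw score, and E-values should be treated as
  indicative.
* Liftover is pairwise and indel-oriented; rearranged or inverted
  references are out of scope.
* Recovery metrics from the repeat-free simulator are an upper bound on
  real-genome performance; repeat-rich backgrounds (an optional stress
  direction) will lower precision for any local-alignment method.
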