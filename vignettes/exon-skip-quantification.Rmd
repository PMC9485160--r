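---
title: "Targeted exon-skipping quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted exon-skipping quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiptally)
```

## The detection model

A spliced mRNA with exons $e_1, \dots, e_n$ has canonical junctions
$(e_i, e_{i+1})$ and, under therapeutic exon skipping, novel junctions
$(e_i, e_{i+2})$ in which the intervening exon is absent. Any read that
contains $k$ consecutive bases crossing a junction point — with at least
`min_overhang` bases on each side — identifies the splice form of its
source molecule unambiguously, provided the probe sequence occurs nowhere
else. `skiptally` therefore reduces splice-form detection to exact
multi-pattern string matching on raw reads: no aligner, no soft-clipping
heuristics, no mapping-quality model.

For a junction with sufficiently long flanking exons there are exactly
$k - 2\,m + 1$ spanning $k$-mers per strand ($m$ = `min_overhang`), 24 at
the defaults $k = 25$, $m = 1$. Exactness matters in two directions:

* **False positives.** A skip-junction probe that also occurs in the
  unmodified transcript (or its reverse complement) would call skipping on
  normal molecules. `design_kmers(screen = TRUE)` removes such probes, and
  probes occurring in another junction's context, recording each removal
  with a reason. This screen is a design choice of the package: plain
  pattern matching has no such protection, and short exons or repetitive
  context make collisions realistic.
* **False negatives.** Exact matching tolerates no mismatches; a
  sequencing error inside a probe kills that probe's match. The 24-fold
  tiling is the mitigation — an error near the junction point can defeat
  all spanning windows, but an error elsewhere leaves most windows intact.
  At a per-base substitution rate of $10^{-3}$ the expected loss of
  junction reads is on the order of 2–3%, negligible for presence/absence
  calls.

Both-strand matching is the default (`strand_mode = "both"`): droplet
chemistry and library preparation differ in whether read 2 is sense or
antisense, and matching reverse complements costs nothing at exact-match
specificity. `strand_mode = "sense"` restricts to stored orientation.

## Chemistry, deduplication and classification

Read 1 of a 10x Chromium 3' v3 record carries a 16-base cell barcode
followed by a 12-base UMI; read 2 is the cDNA fragment. Only read 2 is
scanned. Reads are paired by file order with read-id verification (a
mismatch is a hard, located error: it means the files are
desynchronized), so memory stays constant in file size.

PCR duplicates are reads sharing a (corrected barcode, UMI, junction)
triple; they collapse to one molecule whose `support` is the read count.
Two optional refinements:

* **Barcode correction** against a whitelist rescues barcodes at Hamming
  distance ≤ 1 when the rescue is unambiguous; ambiguous or distant
  barcodes are discarded and counted. Off unless a whitelist is supplied.
* **Directional UMI collapse** (`umi_collapse = "hamming1"`) merges a UMI
  into a strictly higher-support UMI at Hamming distance 1 when
  $\text{support(parent)} \ge 2\,\text{support(child)} - 1$, parents
  processed in decreasing support order with lexicographic tie-breaks.
  The strict inequality keeps equal-support UMIs separate, which makes
  the collapse idempotent: re-deduplicating a molecule table treated as
  single-support hits is the identity. Default is exact matching, the
  conservative choice.

A nucleus is **positive** for a junction if it has at least one unique
molecule of that junction; denominators are all annotated nuclei in the
(condition, cluster) stratum, including zero-count nuclei, and
percentages are reported to two decimals. A single (barcode, UMI)
observed at both a skipping and a canonical junction is biologically
impossible for mutually exclusive splice forms; such molecules are
classified ambiguous and excluded from both classes rather than
fractionally assigned — they signal artifacts, and conservatism costs
little at these frequencies. The `restrict` argument of
`per_cluster_summary()` lets the analyst limit denominators to, e.g.,
mature myonucleus clusters, since which maturity stages should count is a
judgment the package does not make.

## Exact Mann–Whitney inference for small cohorts

Cell-type composition shifts between conditions are tested per cell type
on per-sample percentages with a Mann–Whitney U test. With 3 wild-type
and 8 disease samples, asymptotic p-values are unreliable, so `mw_exact()`
enumerates the exact null distribution of $U$ (the Gaussian-binomial
recursion; `n1 + n2` up to `exact_limit = 25`) whenever the data are
untied. The two-sided p doubles the smaller tail including the observed
point and caps at 1 — conventions differ here, so the rule is stated
explicitly and tested against full enumeration of all
$\binom{n_1+n_2}{n_1}$ rank assignments. Consequences worth knowing:

* the smallest attainable two-sided p for 3 vs 8 is $2/165 \approx 0.012$
  (complete separation), so repeated 0.012 values in a 3-vs-8 screen are
  the floor, not a coincidence;
* at $\alpha = 0.05$ the attainable size is $8/165 \approx 0.0485$, which
  is what the type-I simulation in the test suite checks against.

With ties the exact distribution is no longer the permutation null of the
observed data, so the package switches to the tie-corrected normal
approximation with continuity correction and flags the result
(`method = "normal_tie_corrected"`); no attempt is made to reproduce any
particular software's tie path. Raw p-values are never adjusted by
default; Benjamini–Hochberg is available as an added column.
`recovery_score()` calls a cell type "recovered" when the treated
condition mean is closer to wild type than the disease mean (means by
default, medians by flag) and returns `NA` when disease and wild type do
not differ — a direction cannot be defined there.

## QC filtering

`filter_nuclei()` removes mitochondrial genes by name prefix (`mt-`,
case-insensitive, configurable) *before* computing per-nucleus metrics,
then drops nuclei whose genes-detected (default) or total-UMI value is
strictly below `min_value = 200`. The genes-vs-UMI choice is exposed as
`metric` because both thresholds appear in published practice, sometimes
within one study; the filter report records every step in order so the
provenance of each removal is auditable. Doublet calling is external-tool
territory; `exclude_barcodes` accepts a list of externally called
barcodes and removes them first. MatrixMarket reading validates
dimensions and counts with line-numbered errors and sums duplicate
triplets with a warning.

## What the simulator emulates — and what it does not

`simulate_library()` generates paired gzip FASTQ in v3 chemistry with a
generated barcode whitelist, distinct UMIs per molecule, a configurable
fraction of junction-spanning molecules, per-molecule skip probability per
condition, geometric PCR duplication and per-base substitution errors.
Fragments of junction molecules place the junction point uniformly within
the fragment (or centrally with `junction_placement = "centered"`);
background molecules are drawn from exon interiors, so by construction no
read can contain a skip probe unless its molecule is skipped — the
simulator cannot create false positives, which is exactly what makes it a
usable oracle. Every molecule carries a `detectable` flag (its read
contains at least one full spanning $k$-mer), the quantity the pipeline
can possibly recover.

Defaults are fixed once as the package's study conditions: three
conditions (WT / mdx / mdx_e23AON) with per-molecule skip probabilities
0, 0.01 and 0.10 — a 10-fold treatment contrast over a low disease
baseline, the regime targeted AON readouts operate in — 100 cells per
condition, Poisson(20) molecules per cell, 10% junction overlap, 90 bp
fragments and reads, geometric(0.5) duplication, $10^{-3}$ substitution
rate. The acceptance script scales cells to ~2,000 and switches errors
and duplication off so recovery can be checked for exact equality.

Deliberately not modelled: 3' positional bias (the method is
presence/absence, not coverage estimation), indels (under exact matching
an indel is equivalent to substitutions for hit/miss purposes), empirical
error profiles, ambient RNA and doublets, and full-transcriptome
background. Passing tests therefore demonstrate correctness of the
string-matching, deduplication and counting machinery under clean
assumptions — not robustness to ambient contamination or to
chemistry-specific artifacts in real libraries.

`simulate_frequency_cohort()` draws per-sample compositions from
condition-specific Dirichlet distributions (closure to 100% is exact),
optionally discretised by a multinomial nucleus count;
`simulate_matrix()` plants known below-threshold barcodes and
mitochondrial genes for filter tests.

## Numerical and interface choices

* Exon tables are 1-based inclusive **transcript** coordinates: the
  probes come from the spliced mRNA, so genomic GTF import is out of
  scope by design.
* Probes containing `N` are never emitted and reads' `N` never matches.
* `junction_sequence()` truncates flanks to the exon length rather than
  erroring, so short exons yield fewer (but valid) probes; a junction
  whose probes are all screened away is an error naming the junction.
* Empty strata are reported with `n_nuclei = 0` and an undefined
  percentage rather than an exception; a zero denominator in
  `condition_ratio()` yields `Inf` with an explicit flag.
* Percentages print at two decimals; exact p-values are held at full
  precision internally and printed to three decimals.
* Problem sizes in the shipped tests (~2,000-cell acceptance simulation,
  1,000-read scanner oracle, 1,000-cohort type-I simulation) were chosen
  so the entire suite completes in well under a minute on one CPU while
  keeping Monte-Carlo bounds meaningful.

## Known limitations

Exact matching cannot rescue a read whose only spanning window is hit by
an error; quantification is presence/absence per nucleus, not isoform
abundance; the Mann–Whitney tie path is an approximation flagged as such;
and cluster annotations are taken as given — the package does not
cluster, integrate or call doublets, by scope.
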