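# skiptally

Alignment-free detection and quantification of therapeutic exon skipping in
droplet single-nuclei RNA-seq (snRNA-seq).

## The problem

Antisense oligonucleotides (AONs) can force the spliceosome to exclude a
mutated exon — for Duchenne muscular dystrophy, exon 23 of the mouse *Dmd*
transcript — restoring the reading frame. Whether a given nucleus carries a
skipped transcript is visible directly in the raw reads: a read that spans
the novel exon–exon boundary (e.g. e22–e24, with e23 absent) can only come
from a skipped molecule, while reads spanning the canonical boundaries
(e22–e23, e23–e24) come from unskipped ones. Standard scRNA-seq aligners
quantify genes, not specific junctions, and skipped molecules are rare
(~1% of myonuclei carry a detectable junction read at typical depth), so a
targeted, exact method is needed.

`skiptally` implements that method as a reusable R toolkit:

1. **Probe design** — every k-mer (default k = 25) of the spliced transcript
   that spans a junction of interest, with a cross-reactivity screen that
   removes probes also present in the unmodified transcript (a skipped-form
   probe that occurs in the normal mRNA would create false skip calls).
2. **Raw FASTQ scanning** — exact multi-pattern matching of probes against
   read 2 of 10x Chromium 3' v3 libraries (read 1 = 16 bp cell barcode +
   12 bp UMI), streamed in constant memory; no alignment.
3. **Molecule counting** — PCR duplicates collapse by (barcode, UMI,
   junction); optional barcode whitelist correction (Hamming ≤ 1) and
   directional UMI collapse; molecules classify as skipped / unskipped /
   ambiguous per nucleus, then summarise as percent-positive nuclei per
   condition and cell type.
4. **Cohort statistics** — per-sample cell-type frequency tables and an
   exact Mann–Whitney U test for small cohorts. For group sizes n1, n2 the
   null distribution of U (number of cross-pairs with x > y) is enumerated
   exactly; the two-sided p doubles the smaller tail including the observed
   point, capped at 1. For 3 vs 8 samples the attainable floor is
   2/165 ≈ 0.012. Treatment "recovery" is scored per cell type as the
   treated mean moving closer to wild type than the disease mean.
5. **QC filtering** — sparse MatrixMarket count matrices, per-nucleus
   genes/UMI metrics, removal of mitochondrial genes and nuclei with
   < 200 genes (or UMI) per nucleus.
6. **Simulation** — a seeded 10x-style read simulator with exact
   per-molecule ground truth, so the whole pipeline is testable offline.

## Worked example

Simulate a three-condition cohort (wild type; disease with a 1% per-molecule
skip rate; AON-treated disease at 10%), design probes, scan, deduplicate and
summarise:

```r
library(skiptally)

cfg <- sim_config(n_cells = 200L, molecules_per_cell = 20,
                  junction_overlap_frac = 0.1, error_rate = 0,
                  pcr_geom_prob = NULL)
sim   <- simulate_library(cfg, "demo_sim", seed = 7)
kmers <- design_kmers(cfg$model, cfg$specs)   # 144 probes (both strands)
scan  <- scan_library(sim$paths$r1, sim$paths$r2, kmers)
mol   <- dedup(scan$hits)$molecules           # 1174 unique molecules
summ  <- per_cluster_summary(mol, sim$annotation, junctions = cfg$specs$label)
summ[summ$junction == "e2-e4", ]
#>    condition   cluster junction n_nuclei n_positive percent_positive n_molecules
#>           WT myonuclei    e2-e4      200          0              0.0           0
#>          mdx myonuclei    e2-e4      200          1              0.5           1
#>   mdx_e23AON myonuclei    e2-e4      200         36             18.0          37
condition_ratio(summ, "e2-e4", "mdx_e23AON", "mdx")$ratio
#> [1] 36
```

The skip junction (`e2-e4` in the bundled synthetic transcript) is absent in
wild type, rare in disease, and ~10-fold enriched under treatment — at 200
cells the small untreated count makes the realised ratio noisy (here 36 from
one positive nucleus); at the ~2,000-cell scale used by the acceptance
script it concentrates near the configured contrast, and the recovered
molecules match the simulator's ground truth exactly when the error rate
is 0.

Frequency-table statistics use the exact test:

```r
fit <- mw_exact(c(16, 17, 18), c(1, 2, 3, 4, 5, 6, 7, 8))
fit
#> Mann-Whitney U = 24 (n1 = 3, n2 = 8), two-sided p = 0.012 [exact]
tidy(fit)
#> # A tibble: 1 × 5
#>       U p.value method    n1    n2
#>      24  0.0121 exact       3     8
```

`autoplot()` methods draw junction summaries and cell-type compositions;
`plot_qc()` shows per-nucleus QC distributions.

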