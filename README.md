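# polcoherence

Single-cell RNA-seq of monocyte-derived brain macrophages after traumatic
brain injury shows markers of several polarization programs — M(IL4),
M(LPS,IFNg), M(IL10), M(IC) — in the same tissue. `polcoherence` asks the
question that bulk profiling cannot: is that an **admixture** of distinctly
polarized subsets (cross-class markers mutually exclusive within cells), or
a **mixed state** in which individual cells run several programs at once
(cross-class markers independent within cells)?

The package is an analysis pipeline over cells-by-genes TPM matrices:

* **QC / detection** — cell filtering on aligned reads (>= 1e6) and mapped
  fraction (>= 0.5); gene detectability (TPM > 0.1 in > 50% of cells);
  graded positivity fractions on the TPM ladder 0.1 / 1 / 10 / 100; a
  Mann-Whitney check that marker dropout is not a coverage artefact.
* **Coherence statistics** — pairwise linear regression r² within and
  across classes; positivity splits (TPM > 1 vs <= 0.1) with exact
  small-sample Mann-Whitney tests of whether one marker predicts another.
* **Polarization states** — per-cell combinatorial state calls; counts of
  cells very highly co-expressing (TPM > 100) markers of >= 2 distinct
  classes; a co-occurrence permutation test of cross-class exclusivity
  (odds ratio of the 2×2 positivity table against a within-gene
  permutation null, p = (1+b)/(n_perm+1)) and an
  admixture-vs-mixed-state verdict aggregated over marker pairs.
* **Structure scan** — PCA variance profiles against the randomized-order
  null (each gene's values independently permuted across cells), top
  variable gene selection, and a hierarchical-clustering silhouette scan
  for cell subsets.
* **Synthetic data** — a seeded generator producing 45-cell captures under
  the admixture, mixed-state, and unpolarized-null hypotheses (lognormal
  markers spanning 4–5 orders of magnitude, exact-zero dropout, QC tables
  with a calibrated 18-of-63 failure rate), so every stage is testable
  without downloads.

The central statistic: for markers *a*, *b* of different classes with
positivity calls at a tier *t*, the observed odds ratio of the 2×2 table is
compared with its distribution under independent within-gene permutations —
a null that keeps every gene's marginal distribution (including dropout)
and destroys only cross-gene structure. "Admixture-like" populations show
most pairs significant with OR < 1; "mixed-state-like" populations show
almost none.

## Worked example

```r
library(polcoherence)

d     <- simulate_dataset(sim_config("mixed", n_cells = 45, seed = 7))
panel <- default_marker_panel()

st <- call_states(d$matrix, panel, tier = 100)
count_multiclass_cells(st, min_classes = 2)[c("count", "fraction")]
#> $count
#> [1] 24
#> $fraction
#> [1] 0.5333333

res <- cooccurrence_permutation(d$matrix, panel, n_perm = 999, seed = 7)
admixture_vs_mixed_verdict(res)[c("verdict", "fraction_exclusive_significant")]
#> $verdict
#> [1] "mixed-state-like"
#> $fraction_exclusive_significant
#> [1] 0
```

24 of 45 mixed-state cells (53%) co-express markers of at least two
polarization classes above TPM 100, yet none of the 138 cross-class marker
pairs is more mutually exclusive than the permutation null allows — the
signature separating broadly activated cells from an admixture of
polarized subsets. On an admixture simulation the same pipeline returns
`"admixture-like"` with every pair exclusive-significant.

The numbered scripts under `analysis/` run the full narrative (simulate →
QC/detection → coherence → states/verdict → structure scan) and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_detection.R   # ... through 05_structure.R
```

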