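# podlnc

Integrative lncRNA–mRNA microarray analysis for small two-group
case/control designs, modeled on peripheral-blood profiling of
postoperative delirium (POD; case = delirium, control = matched
non-delirium; the reference cohort is 4 vs 4, GEO accession GSE163943).

The package re-implements the full downstream workflow of such studies as
tested, reusable components, and ships a seeded synthetic-data generator
with planted ground truth so the entire pipeline is exercisable — and its
error behaviour measurable — without any external download.

## What it computes

* **Preprocessing** — detection-flag filter (keep features flagged
  Present/Marginal in ≥ 4 of 8 samples) and quantile normalization: every
  sample column is mapped onto the mean of the order statistics,
  `x̃_(i)j = mean_k x_(i)k`, preserving within-column ranks.
* **Differential expression** — per feature, the pooled two-sample t on
  log2 signal and the linear fold change
  `FC = max(μ_case/μ_ctrl, μ_ctrl/μ_case)`; DE gate `FC ≥ 1.5, p < 0.05`;
  qPCR candidate gates `FC > 2, p < 0.05, intensity > 500`, top 10 per
  direction; microarray/qPCR concordance rate.
* **CNC network** — coding–non-coding co-expression edges for lncRNA–mRNA
  pairs with `|r| ≥ 0.9` and `p ≤ 0.005` (Pearson, all samples pooled);
  at n = 8 the p gate is mathematically redundant (`p(0.9, 8) ≈ 0.0023`).
* **Cis nearby pairing** — DE lncRNA–DE mRNA pairs whose loci lie within
  200 kb (nearest-edge gap, inclusive), with strand-aware
  upstream/downstream labels, intersected with the CNC network.
* **ceRNA triads** — canonical miRNA seed matching (8mer / 7mer-m8 /
  7mer-A1 / 6mer on the reverse complement of mature nt 2–8), miRNA id
  filter (< 1000), shared-miRNA lncRNA–mRNA triads with same-direction
  concordance.
* **Enrichment** — one-sided Fisher exact over-representation against GMT
  gene sets on the 2×2 table (k, n−k; K−k, N−n−K+k), score `−log10 p`.
* **PPI modules** — score-thresholded (≥ 0.7) STRING-like graphs, degree
  hubs (≥ 5 neighbours), and an MCODE-style detector (vertex weighting by
  core-clustering coefficient × k, greedy complex growth, 2-core
  post-processing; cluster score = density × size).
* **Group statistics** — mean (population SD) with pooled t, n (%) with
  uncorrected Pearson chi-square, Shapiro–Wilk normality.

## Worked example

```r
library(podlnc)
run_pipeline("all", outdir = "podlnc_out", config = default_config(seed = 2))
```

Output (one log line per stage):

```
[simulate] 4000 features x 8 samples, 400 planted DE
[preprocess] 3800 of 4000 features pass flags
[de] 388 DE of 3800 features (lncRNA down: 63, mRNA down: 127, lncRNA up: 66, mRNA up: 132)
[cnc] up panel: 245 nodes, 1784 edges
[cnc] down panel: 248 nodes, 1486 edges
[cis] 228 nearby pairs within 200 kb
[overlap] 32 co-expressed nearby pairs
[cerna] 2098 triads (86 lncRNA, 8 miRNA, 162 mRNA)
[enrich] 1 of 9 sets significant at p < 0.05
[ppi] up panel: 5 nodes, 10 edges, 0 hubs, 1 modules
[ppi] down panel: 9 nodes, 17 edges, 6 hubs, 1 modules
[stats] 8 traits compared
[recovery] de 0.94, cnc 0.00, cis 1.00, overlap NA, cerna 0.90
```

Reading this: of 400 planted group shifts, 94% are recalled by the DE
gates; every planted cis neighbour within the 200-kb window is recovered
(`cis 1.00`) and none beyond it; 90% of planted ceRNA triads survive seed
matching plus the direction gate. The `cnc 0.00` row is expected here: the
pipeline's CNC panels use only the top validation candidates as the lncRNA
side (mirroring the study design), while the planted co-expression pairs
live on dedicated non-DE features — they are recovered when `build_cnc()`
is pointed at them directly (see the coexpression tests).

The demographic table of the packaged reference cohort:

```r
demographic_table(pod_cohort(), group_col = "delirium", case_level = "yes",
                  continuous = c("age", "duration_min"),
                  binary = c(cvd = "yes"))
#>   characteristic       type           case        control         p p_fmt
#> 1            age continuous   88.25 (4.76)   83.75 (2.77) 0.2070312 0.207
#> 2   duration_min continuous 141.25 (39.75) 115.00 (36.40) 0.4312305 0.431
#> 3            cvd     binary         3 (75)         1 (25) 0.1572992 0.157
```

These reproduce the published comparison table of the reference cohort at
printed precision (population SDs, pooled t, uncorrected chi-square).

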