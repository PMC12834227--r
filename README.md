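# dargspot

Identification of disease-associated radial-glia-like (DARG) cells and
spots in single-cell and spatial transcriptomic count data.

DARGs are a rare senescence- and interferon-marked glial population defined
by the joint expression of curated marker panels, not by unsupervised
clustering. Locating them — in cells ex vivo or in spatial spots across
multiple-sclerosis lesions — requires a small set of bespoke statistical
steps, which this package implements as tested, reusable components:

* **k-of-n signature voting.** An observation is positive for a signature
  of *n* genes when at least *k* of them reach the per-gene threshold θ on
  log-normalized expression (`vote()`), or are simply detected in
  presence/absence mode. The tolerance form *t = n − k* is used to select
  pseudotime anchor regions (`select_anchor_cells()`).
* **Recovery-AUC scoring.** Per observation, expressed genes are ranked by
  decreasing value — zero-count genes are excluded from the ranking — and a
  signature's enrichment is the area under the step curve
  *c(i)* = #signature genes in the top *i* ranks, *i = 1..T*, normalized by
  the maximum achievable area Σ min(i, m) (`score_signature()`).
* **Permutation background null.** The same scoring with 10,000 random
  gene sets of matched size, pooled over observations; the upper quantile
  is the data-driven confidence threshold (`build_null()`).
* **Dual-criterion DARG-high calling.** A spot is DARG-high when its AUC
  exceeds the null threshold *and* it detects strictly more than 6 (white
  matter) or 4 (gray matter) genes from both the radial-glia and the
  inflammatory signature subsets (`call_darg_high()`), with niche and
  patient-level summaries, quantile-binned Welch t-tests and covariate
  association.
* **Size-penalized module matching.** Gene modules from one dataset are
  matched to another's by Fisher exact tests with Benjamini-Hochberg
  correction; among significant candidates the best match maximizes the
  Ochiai-scaled overlap |A∩B|/√(|A||B|) (`match_modules()`).
* **Synthetic data with planted truth.** Negative-binomial count matrices,
  concentric lesion layouts (core / rim / perilesional / normal-appearing
  white matter) with rim-enriched DARG spots, and paired module
  collections (`simulate_counts()`, `simulate_spatial()`,
  `simulate_module_sets()`), so the full pipeline is testable without any
  external download.

## Worked example

```r
library(dargspot)

sim <- simulate_spatial(seed = 1)           # 60x60 grid, planted rim-enriched DARGs
res <- darg_analysis(sim$matrix, sim$spots, sim$rg_genes, sim$infl_genes,
                     config = default_config())
res
#> darg_result: 3600/3600 spots kept, 109 DARG-high (3.03%)
#>   AUC threshold 0.135246 (q = 0.990, 10000 permutations)

summary(res)
#> DARG-high calls by niche:
#>  niche n_spots n_darg_high    fraction   mean_auc
#>     LC     316           5 0.015822785 0.05005966
#>     LR     704          50 0.071022727 0.06443275
#>   NAWM    1128           6 0.005319149 0.04616178
#>   PLWM    1452          48 0.033057851 0.05419715
```

The AUC threshold is the 99% quantile of 36 million pooled background
scores (10,000 random 40-gene sets × 3,600 spots); 109 spots pass both it
and the >6-genes-from-each-subset gate, and the per-niche DARG fraction
peaks at the lesion rim (LR), the planted enrichment pattern. Against the
planted truth this run has sensitivity 0.99 and precision 0.94.

File-based workflows mirror the in-memory one: `simulate_dataset()` writes
an MTX triplet + spot table + truth + signatures + manifest,
`run_darg_pipeline()` consumes such a directory and writes calls and
summaries, `run_module_matching()` matches GMT module files. A thin CLI
over these lives at `inst/scripts/dargspot-cli.R`
(`simulate | run | match-modules`).

See the vignette (`vignettes/darg-calling.Rmd`) for the model, parameter
defaults (including every published voting rule) and the simulators'
scope.

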