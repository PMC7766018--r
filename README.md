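# spcca — sparse PCA and sparse CCA for paired host–microbiome data

`spcca` integrates two high-dimensional views measured on the same small set
of samples — typically host intestinal gene expression (e.g. from
stool-derived exfoliated epithelial cells) and gut microbial functional
abundances (SEED Level2 categories) — in the regime where features vastly
outnumber samples and classical multivariate methods are infeasible. It is
aimed at microbiome/transcriptome researchers and biostatisticians analyzing
paired-omics designs of a dozen or so subjects.

## What it computes

The engine is the rank-one **penalized matrix decomposition** (PMD)

```
max_{u,v} uᵀ K v   s.t.  ‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1, ‖u‖₁ ≤ c₁, ‖v‖₁ ≤ c₂,
```

solved by alternating soft-thresholded power iterations with exact-zero
loadings, deflation for further components, and a deterministic SVD
initialization. On the standardized cross-product `K = XᵀZ/(n−1)` this is
**sparse CCA** (mutually maximally correlated sparse combinations of two
views); on the standardized data matrix with the budget on the loading side
only it is **sparse PCA**. Around the core sit:

- preprocessing verbs (`log_transform`, `quantile_normalize`,
  `collapse_probes`, `filter_features`, `subset_genes`,
  `standardize_features`), all tibble-in/tibble-out;
- `classical_cca()` (whitening + SVD, with explicit infeasibility errors
  when `n ≤ p + q`) and `subdimensional_cca()`, the exhaustive ranked search
  over all size-k feature subsets;
- `de_test()` — per-feature Welch tests, BH q-values, linear-scale fold
  changes;
- `cca_permutation_test()` and `select_penalties()` for permutation
  calibration and L1-budget choice;
- `sim_scenario()` / `simulate_views()` / `run_comparison()` — a synthetic
  paired-view generator with planted sparse cross-view factors and a
  method-comparison harness;
- pipeline wrappers `run_preprocess()`, `run_analyze()`, `run_simulate()`
  writing TSV results, plots and provenance records.

Fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

Twelve samples (6 breast-fed, 6 formula-fed), a 72-gene expression view and
115 microbial categories, with a 10-gene / 10-category latent factor tied
to the phenotype:

```r
library(spcca)

pv  <- simulate_views(study_scenario("scfa", effect = 3, seed = 1))
fit <- sparse_cca(pv$x, pv$z, c1 = sqrt(10), c2 = sqrt(10))
fit
#> Sparse CCA: 2 components, budgets (3.162, 3.162)
#>   comp1: canonical correlation 0.990, membership 12 (x) / 14 (z)
#>   comp2: canonical correlation 0.950, membership 12 (x) / 13 (z)

support_recovery(fit$u[, 1], pv$truth$support_x)
#> # A tibble: 1 × 4
#>   support_tpr support_fpr support_precision support_f1
#>         <dbl>       <dbl>             <dbl>      <dbl>
#> 1           1      0.0323             0.833      0.909

separation_statistic(fit$scores_x[, 1], pv$x$label)
#> [1] 0.0004647008

de_test(pv$x, values_are_log = FALSE) |> dplyr::filter(q < 0.05) |> nrow()
#> [1] 3
```

Component 1 finds all ten planted genes plus two spurious ones (TPR 1,
F1 0.91, canonical correlation 0.99) and its scores split the two feeding
phenotypes at p ≈ 5e-4, while univariate testing flags only 3 genes —
the coordinated multivariate structure is far more visible to sCCA than to
per-gene tests, and with a weaker per-gene amplitude the univariate list is
typically empty (see the vignette). `autoplot(fit, view = "x")` draws the
component-1 vs component-2 score plot with points colored by the microbial
view's first-component score.

## Package layout

`R/` implementation · `tests/testthat/` unit, property, and acceptance
tests · `vignettes/sparse-two-view-integration.Rmd` methods notes ·
`scripts/acceptance.R` reproduction script.
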