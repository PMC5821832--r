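# kquadrant

Extracting important variables from **non-linear unsupervised structure**
in metabolic profiling data.

Linear PCA is the workhorse of NMR-based metabolomics, but when the
grouping of samples is a non-linear function of the measurements (e.g.
driven by diet or physiology), linear score plots concentrate samples and
any grouping read off them is biased — and kernel methods, which do capture
such structure, cannot say *which variables* carry it. `kquadrant`
implements a complete workflow that closes this gap, for analysts working
with peak-picked NMR intensity tables, element concentration panels
(ICP-OES) and parallel dietary/nutrient records:

1. **Preprocess** — probabilistic quotient normalization (PQN) of raw
   spectra, auto scaling, block merging (`pqn_normalize`, `autoscale`,
   `merge_blocks`, plus a simple `peak_pick` utility).
2. **Embed** — kernel PCA with the ANOVA kernel
   `K(x, y) = (Σₖ exp(−σ (xₖ − yₖ)²))ᵈ`
   (degree d = 1 by default), with a bandwidth scan over σ ∈ [0.05, 0.30]
   and a score-plot dispersion criterion (`kpca_fit`, `scan_sigma`).
3. **Pseudo-label** — four classes from the signs of (PC1, PC2)
   (`quadrant_labels`).
4. **Rank variables** — a conditional permutation importance forest
   (Strobl-style within-stratum permutation, CART base learners on
   0.632 subsamples without replacement), validated by leave-one-out
   cross-validation (`fit_forest`, `conditional_importance`, `loocv`).
5. **Validate** — tie-corrected Kruskal–Wallis tests across the four
   classes (`kruskal_wallis`, `group_summaries`).
6. **Associate** — median-split discretization, exact Apriori mining, rule
   filtering at support ≥ 0.0625, confidence ≥ 0.25, lift ≥ 1.2, and
   SIF/GraphML network export for Cytoscape (`discretize`, `mine_rules`,
   `export_network`).

A seeded synthetic-study generator with known ground truth
(`generate_study`) makes every stage testable end to end; see the methods
vignette (`vignettes/kquadrant-methods.Rmd`) for the model, parameter and
design rationale.

## Worked example

```r
library(kquadrant)

study <- generate_study(n = 120, p = 30, n_informative = 6,
                        n_planted = 4, seed = 42)
res <- run_pipeline(
  study$features, study$nutrients,
  pipeline_config(forest = forest_config(ntree = 40, seed = 42),
                  top_n = 10L, max_len = 2L),
  out_dir = "run")
```

The run directory gets every intermediate as plain text (`matrix.tsv`,
`sigma_scan.tsv`, `scores.tsv`, `importance.tsv`, `confusion.tsv`,
`kw.tsv`, `rules.tsv`, `network.sif`, `network.graphml`, `config.json`,
`log.txt`). Inspecting the in-memory results:

```r
res$kernel
#> kernel_spec: anova (sigma = 0.3, degree = 1)
res$labels
#> quadrant_labeling: class 1: n=28, class 2: n=35, class 3: n=31, class 4: n=26
res$cv
#> cv_report: accuracy 95.8% over 120 samples
#>     predicted
#> true  1  2  3  4
#>    1 27  0  0  1
#>    2  0 35  0  0
#>    3  0  3 28  0
#>    4  1  0  0 25
head(res$top, 5)
#>   variable modality importance rank
#> 1    met04      nmr     0.1017    1
#> 2    met06      nmr     0.0443    2
#> 3    met05      nmr     0.0392    3
#> 4    met01      nmr     0.0330    4
#> 5    met03      nmr     0.0210    5
head(res$kw, 3)
#>   variable   H df  p_value tier
#> 1    met04 109  3 1.74e-23  ***
#> 2    met06 109  3 2.23e-23  ***
#> 3    met05 108  3 3.15e-23  ***
head(res$rules, 3)
#>   antecedent consequent support confidence lift
#> 1 met01=high  met05=low   0.483      0.967 1.93
#> 2  met01=low met05=high   0.483      0.967 1.93
#> 3 met05=high  met01=low   0.483      0.967 1.93
```

Reading the output: the σ scan picked 0.30 as the most dispersed
embedding; the quadrant pseudo-classes it induces agree with the
generator's hidden classes at Rand index 0.95; LOOCV re-predicts the
pseudo-classes at 95.8% with a near-diagonal 4×4 confusion matrix; the
truly informative variables (`met04`, `met06`, ...) top the conditional
importance ranking and carry *** Kruskal–Wallis stars; and the rule list
surfaces strongly co-varying variable pairs (lift ≈ 1.9 against
independence at 1.0).

## Command line

```sh
exec/kquadrant simulate --n 400 --p 100 --informative 8 --seed 7 --out-dir sim
exec/kquadrant run-all --in sim/features.tsv --nutrients sim/nutrients.tsv \
    --seed 7 --out-dir run
```

Other subcommands: `preprocess`, `kpca`, `scan`, `labels`, `importance`,
`loocv`, `kw`, `mba` (each has `--help`).

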