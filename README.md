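# gramcoord

Spectral coordination analysis of the BAG2–HSC70–STUB1–MAPT protein-folding
network across Alzheimer's disease severity stages.

Tau (MAPT) homeostasis depends on a small chaperone circuit: HSC70 folds
tau clients, BAG2 is its nucleotide-exchange factor, and STUB1 (CHIP)
routes misfolded clients to degradation. `gramcoord` quantifies how the
*joint coordination* of this four-gene panel changes across the severity
stages of a hippocampal microarray cohort (control / incipient / moderate /
severe, groups of 9/7/8/7 as in GSE1297), and builds the predictive models
that sit on top of the panel. It is written for computational biologists
who want every step of that analysis reproducible and testable without the
original accession downloads.

## What it computes

For each severity group the panel submatrix `X` (4 genes × n samples,
log10 scale, `x = log10(g + 1)`) is summarized by its **uncentered Gram
matrix** `R = X Xᵀ` of gene–gene dot products. The eigenvalues of `R`,
normalized to fractions `λᵢ / Σλₖ`, measure how concentrated the panel's
joint variation is; the **leading fraction** `λ₁/Σλₖ ∈ [1/4, 1]` is the
coordination index (reported to rise from ≈0.56 in controls to ≈0.79 in
the severe stage), and the leading eigenvectors of two stages are compared
by their dot product — a negative alignment is a sign reversal of the
dominant coordination direction. No centering and no scaling are applied:
the shared mean component is part of the statistic.

Around this core the package provides

- `screen_genes()` — gene-wise Welch/Student t screen with up/down calls
  at raw p < 0.05;
- `spearman_matrix()`, `soft_adjacency()` (`|ρ|⁸`), `detect_modules()`,
  `module_eigengenes()`, `module_trait_correlation()` — a simplified
  soft-threshold co-expression module stage (β = 8, min size 30, merge
  cut 0.25);
- `nn_train()` / `nn_evaluate()` — a from-scratch 4–32–1 sigmoid network
  (linear output) trained by per-sample SGD on squared error to predict
  MMSE from the panel;
- `extract_features()`, `rbf_map()`, `svm_train()`, `roc_curve()` — a
  from-scratch RBF-landmark max-margin classifier over (sum, SD) panel
  features (σ² = 0.5), with ROC/AUC from sensitivity p/(p+n) and
  specificity t/(f+t);
- `simulate_panel()`, `simulate_mmse()`, `simulate_classification_cohort()`,
  `simulate_background_modules()` — seeded generators that plant every
  structure the stages assume;
- `run_pipeline()` — the six stages end to end with a JSON report.

The methods vignette (`vignettes/gramcoord-methods.Rmd`) documents the
model, the sign conventions, every tunable default and the deliberate
simplifications.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_spectral_coordination.R
# ... through analysis/06_disease_classifier.R
```

`02_spectral_coordination.R` prints, for a cohort with planted leading
fractions 0.56/0.58/0.60/0.79:

```
Leading eigenvalue fraction by severity stage:
  control incipient  moderate    severe
    0.543     0.572     0.597     0.808
Consecutive deltas: 0.029 0.025 0.211
The jump concentrates in the final (severe) transition: severe
  control leading fraction 0.543 (bootstrap 95% CI 0.510-0.750)
  severe leading fraction 0.808 (bootstrap 95% CI 0.787-0.925)
Published control-vs-severe leading-vector alignment: -0.9442 (reversed: TRUE)
```

— the estimated coordination index is flat across the first three stages
and jumps in the severe stage, matching the planted trajectory within
small-sample noise (the bootstrap intervals show how wide n = 7–9 groups
leave the estimate), and the shipped published eigenvector tables
(`reference_eigenvectors()`) reproduce the reported control-vs-severe
sign reversal with alignment ≈ −0.944.

Or, in a session:

```r
library(gramcoord)
sim <- simulate_panel(panel_sim_config(seed = 1))    # 9/7/8/7 cohort
gp  <- grouped_panel(sim$expression, sim$metadata)
srs <- lapply(names(gp$groups), function(g)
  eigendecompose(gram_matrix(gp$groups[[g]], group = g)))
coordination_trajectory(srs)
#> <coordination_comparison>
#>   leading fractions: control=0.557, incipient=0.568, moderate=0.607, severe=0.764
```

Downstream, `analysis/05_mmse_network.R` reports a held-out Pearson r of
0.930 (n = 7) for MMSE prediction, and `analysis/06_disease_classifier.R`
a verification AUC of 0.900 (361 training / 31 verification samples,
planted per-axis separation δ = 1.5).

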