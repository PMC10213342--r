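---
title: "Methods: spectral coordination of a chaperone gene panel across Alzheimer's severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral coordination of a chaperone gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gramcoord)
```

## The scientific question

Tau (MAPT) homeostasis in the brain depends on a small chaperone circuit:
HSC70 (gene symbol HSPA8) folds tau clients, BAG2 acts as its nucleotide
exchange factor, and STUB1 (CHIP) is the E3 ubiquitin ligase that routes
misfolded clients to degradation. `gramcoord` asks whether the *joint
coordination* of this four-gene panel — BAG2, HSC70, STUB1, MAPT — degrades
as Alzheimer's disease progresses through the severity stages control,
incipient, moderate, severe (hippocampal microarray cohorts such as
GSE1297, groups of 9/7/8/7 samples).

The package implements five analysis stages around that question, plus
synthetic-data generators that plant every structure the stages assume, so
the whole pipeline is verifiable without downloading the cohort data.

## The coordination statistic

Raw intensities $g_{ij}$ are transformed once, elementwise:

$$x_{ij} = \log_{10}(g_{ij} + 1),$$

and the matrix is split into per-group panel submatrices $X_g$
($4 \times n_g$). For each group the **uncentered Gram matrix**

$$R = X_g X_g^\top, \qquad R_{ij} = \langle x_i, x_j \rangle$$

collects plain dot products between gene rows — deliberately *not*
mean-centered and *not* scaled. The shared mean component of the panel is
part of the signal; this is what distinguishes the statistic from
covariance PCA, and a `centered = TRUE` diagnostic flag exists but defaults
off. $R$ is symmetric positive semi-definite; it is symmetrized as
$(R + R^\top)/2$ before the symmetric eigensolver runs.

Eigenvalues are reported as fractions of their sum,
$\lambda_i / \sum_k \lambda_k$, sorted descending. The **leading fraction**
$\lambda_1/\sum_k\lambda_k \in [1/4, 1]$ is the coordination index: values
near 1 mean the four genes move along a single joint direction. The
reported trajectory rises from about 0.56 (control) to about 0.79
(severe), with the jump concentrated in the final transition; the
synthetic generator's default spectra (0.56, 0.58, 0.60, 0.79) mirror
exactly that pattern.

Equivalently, the fractions are the normalized squared singular values of
$X_g$; that identity is the independent oracle the test suite checks
against.

### Eigenvector sign conventions

Eigenvectors are defined only up to sign, so three variants are kept:

* `vectors_raw` — as the solver returned them; used when comparing against
  externally printed tables.
* `vectors` — reporting convention: each column flipped so its
  largest-magnitude component is positive.
* `vectors_profile` — each column flipped so its dot product with the
  group's mean expression profile (`rowMeans(X)`) is nonnegative.

The profile anchor matters for one subtle reason: $X$ and $-X$ produce the
*same* Gram matrix, so no information in $R$ alone can distinguish a
planted leading direction $v$ from $-v$. A cross-group "sign reversal" is
therefore only identifiable when each group's vector is oriented against
its own data; `compare_leading_vectors()` uses the profile-anchored
vectors whenever both arguments carry a profile, and the raw vectors
otherwise (plain numeric columns, such as published eigenvector tables,
are compared exactly as given). The package ships the previously reported
control and severe eigenvector matrices
(`reference_eigenvectors()`); the dot product of their leading columns is
$\approx -0.944$, the published reversal.

Tied eigenvalues (relative gap below $10^{-12}$) are ordered within the
tied block by descending first-component magnitude, and eigenvectors
inside a tied block are documented as non-unique. A Gram matrix with zero
trace (an all-zero panel) is rejected as degenerate. Because per-group
sample sizes are 7–9, `bootstrap_leading_fraction()` offers a
column-resampling confidence interval as a clearly labelled stability
extension (off the main path).

## Differential expression

`screen_genes()` runs gene-wise two-sample t tests between pooled AD
samples and controls with up/down calls at raw $p < 0.05$ (strict
inequality). Defaults:

* **Welch variant** — unequal variances are the safe assumption at group
  sizes of 7–9; the pooled-variance Student test is available to probe
  sensitivity.
* **No multiple-testing correction** — matching the original raw-threshold
  screen; Benjamini–Hochberg is available (`adjust = "BH"`) but off by
  default and labelled an extension.
* Zero-variance corner cases are explicit: equal constant groups give
  $t = 0, p = 1$; unequal constant groups give $p = 0$ with a warning.

A null simulation (5 000 standard-normal genes at 9-vs-7) keeps the
empirical significant fraction in $[0.03, 0.07]$, the calibration the test
suite enforces.

## Co-expression modules (simplified)

The module stage follows the weighted co-expression recipe with the stated
settings — Spearman correlation, soft power $\beta = 8$
($a_{ij} = |\rho_{ij}|^\beta$; the absolute value is a no-op at even
$\beta$ and keeps odd powers in $[0,1]$), minimum module size 30, merge
cut height 0.25 — but it is deliberately **not** a faithful WGCNA port:

* Clustering runs on the distance $1 - a_{ij}$ (average linkage), not on
  topological overlap; TOM is out of scope and the deviation is stated
  here prominently.
* The dynamic tree cut is replaced by a **static cut at height 0.995**
  plus two filters: clusters below the minimum size, and clusters whose
  mean within-cluster adjacency falls below 0.01, go to the sink module
  `"unassigned"`. The coherence floor is what sends structureless noise
  clusters to the sink, the role the dynamic cut's internals play in the
  original. The 0.995 default reflects the geometry at $\beta = 8$:
  structureless pairs have adjacency within $10^{-4}$ of zero (distance
  $\approx 1$), while coherent blocks finish merging well below the cut.
  An earlier candidate default — a high quantile of the merge heights —
  was discarded because all between-block merge heights pile up within
  $10^{-4}$ of 1, so any quantile cut lands above them and collapses
  everything into one cluster.
* Modules whose eigengenes (first right singular vector of the
  gene-standardized submatrix, sign-anchored to the module's mean profile)
  correlate above $1 - \text{merge cut} = 0.75$ merge iteratively until
  stable. Merging needs expression values, which the adjacency matrix does
  not carry, so `detect_modules()` takes an optional `expr` argument and
  skips merging without it.
* Labels are deterministic (`module_1`, `module_2`, … by decreasing
  size); colour names are cosmetic aliases in the field and not used.

`pick_soft_power()` reports the signed scale-free fit $R^2$ (log-log
regression of binned connectivity frequency, negated for positive slopes)
and mean connectivity per candidate power, choosing the smallest candidate
reaching 0.8. Module–trait relationships are Pearson correlations between
module eigengenes and numerically coded traits (severity group 1–4, sex
0/1, Braak ordinal).

On planted cohorts (3 modules × 40 genes, within-module correlation 0.8,
30 samples) recovery is essentially exact (adjusted Rand index ≥ 0.98 in
the shipped analyses), and independent noise genes all land in the sink.

## The MMSE network

A from-scratch feedforward network maps the four panel values to the
Mini-Mental State Examination score (0–30, lower = more impaired):

$$y = b + c^\top a, \qquad a_i = \mathrm{sigmoid}(k_i + W_i x), $$

with a 32-unit sigmoid hidden layer and a **linear output** (no output
nonlinearity — enforced). Choices, with the reasoning:

* **Normalization**: per-feature min–max to $[0,1]$, bounds fit on the
  training samples only (z-scoring is available).
* **Initialization**: uniform $(-r, r)$ with $r = \sqrt{6/(f_{in} +
  f_{out})}$ per layer, biases zero, fully seeded.
* **Training**: per-sample stochastic gradient descent on squared error,
  learning rate 0.05, 2 000 epochs, visit order reshuffled each epoch from
  a seeded stream — identical seed and data give bitwise-identical
  parameters. Divergence (non-finite loss) aborts with a pointer to the
  learning rate. Early stopping is off by default.
* The analytic gradient is exported (`nn_gradient()`) because the
  finite-difference check of that gradient is the central correctness test
  of any hand-written network; the suite verifies it to $10^{-5}$
  relative.

Evaluation reports Pearson and Spearman correlation (two-sided Pearson
$p$); predictions are clipped to $[0, 30]$ for reporting only, with
unclipped values retained.

A caveat the tests make visible: with 24 training samples and 193
parameters the network interpolates training noise (training MSE near
zero), so held-out $r$ fluctuates more than the noise level alone would
suggest. Under the synthetic conditions (MMSE = linear(panel) + N(0,1),
24/8 seeded shuffled split) roughly nine in ten seeds reach held-out
$r \ge 0.9$; no regularization was added because the defaults above are
part of the studied configuration.

## The disease classifier

Each sample is reduced to two panel features — the **sum** and the
**standard deviation** of its four log-expression values (population
denominator 4 by default, configurable to the sample convention;
both statistics are symmetric in the genes). The classifier then:

1. z-scores the features with training-set statistics (Gaussian
   similarities are scale-sensitive);
2. maps every sample to its vector of RBF similarities
   $\exp(-\lVert x - l \rVert^2 / 2\sigma^2)$ to a landmark set —
   by default all training samples, the standard landmark construction;
   a k-means reduction is available for low-dimensional illustration;
   $\sigma^2 = 0.5$ by default;
3. trains a soft-margin linear separator on the mapped features by
   deterministic full-batch subgradient descent on
   $\tfrac12\lVert W\rVert^2 + C\sum_i \max(0, 1 - y_i(W y^{(i)} + B))$
   (maximizing the margin $1/\lVert W\rVert^2$), step size $1/t$ — the
   classical schedule for a 1-strongly-convex objective — keeping the
   better of the last and the averaged second-half iterate. $C = 1$ by
   default. On reference problems the objective lands within 1% of an
   established convex QP solver, which the tests verify.

ROC curves are built from the confusion definitions sensitivity
$= p/(p+n)$ and specificity $= t/(f+t)$ (p = true positives, n = false
negatives, t = true negatives, f = false positives), sweeping the
threshold over sorted unique decision values (tied scores move as one
step) and integrating by the trapezoid rule; the result equals the
normalized Mann–Whitney statistic to $10^{-10}$.

## Synthetic generators

All generators are pure functions of their seed.

* `simulate_panel()` plants per-group Gram spectra exactly:
  $X = \sum_k \sqrt{\mu_k}\, q_k w_k^\top + \text{noise}$ with orthonormal
  $q_k$ (gene space; $q_1$ is the planted leading direction) and $w_k$
  (sample space; $w_1$ strictly positive so the mean profile carries the
  leading direction's sign). Spectra are planted in the *uncentered* Gram
  sense — the planted direction includes the mean component. Defaults are
  the study conditions: group sizes 9/7/8/7, leading fractions
  0.56/0.58/0.60/0.79 with the remaining mass split 50/30/20, noise SD
  0.02 on unit total trace. In `"raw"` mode the log matrix is
  back-transformed through $g = 10^x - 1$ so the pipeline's log step is
  exercised end to end; this requires an entrywise-nonnegative $x$, which
  is achieved by re-drawing the orthonormal complements rather than by an
  additive shift (a shift would change the spectrum). Raw mode therefore
  needs concentrated spectra (leading fraction ≳ 0.8) and errors
  otherwise instead of silently distorting the target.
* `simulate_mmse()` draws MMSE = clip(intercept + coeffs·x + N(0, sd), 0,
  30), rounded to integers. With `coeffs = NULL` the coefficients are
  calibrated deterministically so the noiseless predictor has mean 18 and
  SD 7 — a realistic spread for a mixed-severity cohort.
* `simulate_classification_cohort()` samples (sum, SD) features from two
  bivariate normals whose means differ by $\delta$ standard deviations
  **along each feature axis** (total Mahalanobis separation
  $\delta\sqrt2$ for independent axes; at $\delta = 1.5$ the Bayes-optimal
  AUC is about 0.93). This per-axis reading was chosen over "$\delta$
  total Mahalanobis" because only it makes the intended recovery behaviour
  (test AUC ≥ 0.9 at $\delta = 1.5$) attainable even in principle. Panel
  values are back-constructed from the features along the fixed pattern
  $(1,-1,1,-1)$, so feature extraction recovers the sampled features
  exactly. Default class sizes 180/181 mirror the external training
  cohort design, with a 16/15 verification cohort.
* `simulate_background_modules()` builds per-module latent factors with
  gene loadings giving within-module correlation $\rho$ (default 0.8),
  plus independent noise genes; a factor can be tied to a clinical trait.

What the generators deliberately do **not** emulate: probe-level
Affymetrix noise, heavy-tailed intensity distributions, batch structure,
gene-gene correlation between the panel and the background, and
missingness (panel rows with missing entries abort with an error, since
the analysed cohorts have none). Passing tests on these cohorts therefore
demonstrates correctness of the computations and recoverability of planted
structure — not robustness to every artefact of real microarray data.

## Problem sizes and numerical choices

The shipped analyses and the test suite run at the study's own scales:
4-gene panels over 9/7/8/7 groups; 200 replicates for spectral recovery;
5 000 genes for the null screen; 160 genes × 30 samples for module
recovery; 20 seeded replicates for the network (24/8 split) and the
classifier (361 train / 31 test). Numerical tolerances follow the
object invariants: symmetry and PSD checks at $10^{-9}$–$10^{-10}$
relative, spectral reconstruction at $10^{-8}$, oracle agreements at
$10^{-8}$–$10^{-12}$ as stated above.

## Known limitations

* The probe-to-gene mapping behind the published panel values is not
  recoverable from the source material; `map_probes_to_genes()` defaults
  to the max-mean convention and accepts pinned probes (`listed_probe`)
  to reproduce any specific choice. HSPA8 is accepted as an alias for
  HSC70 in mapping tables.
* The module stage is a documented simplification, not WGCNA; full
  real-data module inventories (dozens of modules on 22 283 genes) are
  out of its intended scope.
* Reproducing the published real-data endpoints (held-out $r = 0.915$ for
  MMSE, cross-study AUC = 0.72) requires the original accession data and
  unstated splits; the analysis scripts reproduce the *design* on
  synthetic cohorts instead, and the published eigenvector tables are the
  only external numbers shipped with the package.
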