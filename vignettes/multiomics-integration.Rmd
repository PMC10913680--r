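---
title: "Sparse multi-block integration of multi-omics data with omiclink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-block integration of multi-omics data with omiclink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiclink)
```

## Scope and model

omiclink integrates two or more omics tables (metabolite quantities, 16S/ITS
amplicon counts, normalized transcript abundances, proteomics, ...) measured
on the same samples, following a three-step workflow: (1) ingest and
pre-filter each table, (2) select informative features per table with a
sparse single-omics model and reduce the table accordingly, (3) integrate the
reduced tables pairwise (sparse PLS) or jointly (supervised multiblock
sPLS-DA) and export cross-block feature association networks.

All latent models share one template. For blocks $X_k \in \mathbb{R}^{n
\times p_k}$ (column-centered and unit-variance scaled), each component $h$
finds per-block weight vectors $a_k$ with $\|a_k\|_2 = 1$ and at most
$\mathrm{keep}_k[h]$ nonzero entries, maximizing a covariance objective
between the block scores $t_k = X_k a_k$:

* **sparse PCA** — one block, maximize $\mathrm{var}(t)$; solved by
  soft-thresholded power iteration on the residual matrix.
* **sparse PLS** (two blocks, regression or canonical mode) — maximize
  $\mathrm{cov}(t, u)$ with $t = Xa$, $u = Yb$; NIPALS alternation with both
  weight vectors soft-thresholded to exact support sizes. Regression mode
  deflates both blocks on the $X$-scores ($Y$ is residualized against $X$,
  so swapping the datasets changes the result); canonical mode deflates each
  block on its own scores.
* **sPLS-DA** — sparse PLS in regression mode against the one-hot dummy
  coding of the class labels; the dummy side is never sparsified.
* **multiblock sPLS-DA** — block-coordinate ascent maximizing
  $\sum_{k<j} c_{kj}\,\mathrm{cov}(t_k, t_j)$, where the design matrix
  $c$ weights block pairs and the dummy class block joins with weight 1 to
  every data block. Each block is deflated on its own scores.

The sparsity operator keeps exactly `keep` nonzeros: weights are
soft-thresholded at the (keep+1)-th largest magnitude; magnitude ties at the
boundary are resolved toward earlier columns, which survive with a vanishing
weight so the support size is exact. Every loading column is sign-fixed so
its largest-magnitude entry is positive, making fits comparable across runs.

## Pre-filtering

Three upload-time filters, applied automatically by `prefilter()`:

* **Low-count filter** — drop features whose column sum is strictly below 10.
* **MAD cap** — if a table holds more than 10,000 features, apply the
  low-count filter, then remove the columns with the smallest median
  absolute deviation (no consistency constant; ranking-invariant) until
  exactly 10,000 remain. Ties keep earlier columns.
* **Microbiome (compositional) preprocessing** — for count tables flagged as
  microbiome: remove features whose total count is at or below 0.01% of the
  grand total, add a pseudo-count of 1, total-sum scale each sample, and
  apply the centered log-ratio transform; rows then sum to zero. The
  threshold comparison (`<=` vs `<`) and offset order are configurable
  because upstream descriptions leave them ambiguous; the defaults are
  `<=` on raw totals with the offset added after filtering. Total-sum
  scaling does not change CLR output (CLR is scale-invariant per sample);
  it is kept for provenance clarity.

Missing values are a hard error everywhere: imputation belongs upstream and
silently imputing inside an integration tool would hide a modeling decision.

## Tuning rules

* **Components, unsupervised path**: the smallest number of principal
  components reaching 80% cumulative explained variance.
* **Components, two-block path**: per-component cross-validated
  $Q^2_h = 1 - \mathrm{PRESS}_h / \mathrm{RSS}_{h-1}$, pooled over response
  columns; the selected count is the last component with $Q^2 > 0.0975$
  (i.e. $1 - 0.95^2$), falling back to one component.
* **Components, discriminant paths**: cross-validated balanced error rate
  (BER, the mean of per-class misclassification rates) with the centroids
  prediction distance; ties prefer fewer components.
* **Feature counts**: tuned sequentially per component. Discriminant models
  minimize CV BER over a keep grid (ties: smaller keep). Two-block models
  maximize the mean absolute correlation between cross-validation-predicted
  and full-fit component scores, averaged over the X and Y sides (the rule
  is stated without a side upstream; averaging both is symmetric and
  documented here as our choice). The multiblock keep search covers the
  cartesian product of the per-block grids for each component.

Defaults: folds = `min(5, smallest class size)` (a 12-sample, 4-class
experiment forces 3), repeats = 10, keep grid `{1..10, 15, 20, 25, 30, 40,
50}` truncated at the feature count, and a mandatory integer seed — the
entire tuning stack is a pure function of (data, parameters, seed).

## The near-zero-variance repair loop

Cross-validated tuning can fail when a training fold contains a
zero-variance feature column (scaling divides by zero). `nzv_repair()`
catches this failure class, computes the percentage of distinct values for
every column of the implicated dataset(s), removes from the dataset holding
the global minimum all columns attaining that minimum, and restarts the
computation — repeating until success or until a dataset drops below 2
features, at which point it aborts with the accumulated repair log. The log
(iteration, dataset, removed ids, uniqueness) is part of every tuning
artifact, so the silent automation is fully auditable.

Iteration-cap exhaustion in the sparse solvers is deliberately *not* such a
failure: with aggressive sparsity on very small training folds the NIPALS
alternation can cycle between competing supports indefinitely. Any point of
such a cycle is a reasonable stationary solution, so after `max_iter` (500;
tolerance 1e-9 on the maximum absolute loading change) the current iterate
is returned deterministically with a `converged` flag. Routing these events
into the repair loop would remove arbitrary columns from datasets whose
columns are all unique — the repair mechanism is meant for degenerate
columns, not for optimizer limit cycles.

## Design matrix

For the multiblock model the design matrix is data-driven by default: every
block pair gets a dense canonical one-component PLS fit, the absolute
correlation between the two component-1 scores is recorded, and the minimum
over pairs — rounded down to the nearest tenth — fills every off-diagonal
cell. The raw minimum is retained in the result, flooring can be disabled,
and a manual scalar always overrides the computed value (prior biological
knowledge beats a data-driven default).

## Class prediction

Discriminant models predict by projecting new samples onto the model scores
(replaying the training deflation) and assigning the class by one of three
distances: `max` (argmax of the predicted dummy response), `centroids`
(nearest training-class score centroid, the default and the distance used in
all BER tuning), or `mahalanobis` (nearest centroid under the pooled
within-class score covariance, ridge-stabilized). Multiblock models combine
per-block predictions by majority vote; ties go to the block whose
component-1 scores correlate most strongly with the class dummy matrix.

One numerical subtlety is worth recording: the centered dummy matrix of $K$
classes has rank $K-1$, so deflating the class block on its own scores
exhausts it after $K-1$ components. Fitting more components than that is
common practice (e.g. seven pre-selected components with four classes), so
once the class block is exhausted it drops out (zero loading and score) and
the remaining components are driven purely by the design-weighted
inter-block covariances. They behave like unsupervised components and are
simply not selected when they do not reduce the BER.

## Association networks

For blocks $a, b$ of a fitted model the similarity score is
$M_{ij} = \sum_{h \le H} \mathrm{cor}(x_i, t^a_h)\,\mathrm{cor}(y_j, t^b_h)$,
each variable correlated with its *own* block's scores (for two-block PLS:
the X-scores and Y-scores). When within-block scores are orthogonal the
scores are bounded by 1 in absolute value. `build_network()` keeps edges
with $|M_{ij}|$ strictly greater than the cutoff and drops isolated nodes;
edge sets are therefore monotone non-increasing in the cutoff.
`circos_edges()` unions all block pairs of a multiblock model and attaches
per-feature class-mean profiles (standardized scale) for circos-style
rendering. Networks export to GraphML (via igraph) or JSON with block and
color attributes, round-tripping weights at full double precision.

## Synthetic data: what it emulates and what it does not

`generate_multiomics()` draws per-sample latent factors as a class mean plus
standard normal noise; class means sit on the vertices of a regular simplex
with pairwise distance 2 (equal spacing requires `shared_factors >= K - 1`).
Each block observes the factors through a sparse loading matrix that is
nonzero only on its `n_informative` features (unit-magnitude loadings with
random signs). The per-block `loading_strength` scales the class-mean part
of the factors seen by that block, so strength 0 removes exactly that
block's class signal while the shared factor noise remains — cross-validated
BER then sits at the chance level $(K-1)/K$, and larger strengths
monotonically lower it. Continuous blocks add Gaussian noise (`noise_sd`);
count blocks are per-sample multinomial draws of `library_size` reads
(default 50,000, a typical amplicon depth) with probabilities
`softmax(baseline + eta)`, where the seeded per-feature baseline
(log-normal, sd 1.5) reproduces the heavy-tailed abundance distribution of
real ASV tables and gives the low-count filter realistic work.

Not emulated: zero-inflation beyond multinomial sparsity, phylogenetic or
ecological correlation structure among taxa, batch effects, and
block-specific sample dropout. A green recovery test therefore establishes
that the estimators find planted low-rank structure at realistic sizes and
noise — not that they are robust to every pathology of real microbiome data.

`case_study_spec()` ships a fixture shaped like a typical four-class,
twelve-sample experiment with blocks of 23 (targeted metabolomics), 779 and
290 (16S and ITS after compositional filtering) and 10,000 (capped
transcriptomics) features.

## Numerical choices and degenerate inputs

* Standardization treats a column with standard deviation below 1e-12 as
  zero-variance (a repairable failure during tuning, a plain error in a
  direct fit, naming the column).
* `floor_tenth()` adds 1e-9 before flooring to absorb binary representation
  error (0.7 must floor to 0.7, not 0.6).
* The Mahalanobis distance adds a 1e-8 ridge to the pooled within-class
  score covariance, which may be singular with few samples per class.
* Harmonization orders samples ascending lexicographically — an arbitrary
  but fixed convention that makes fold assignment, and hence every tuned
  result, reproducible.
* All tie-breaks (keep grids, component counts, sign conventions, vote
  resolution) are deterministic and documented at the function level.

## Limitations

The solvers target the small-$n$, moderate-$p$ regime of integrative omics
studies (tens of samples, up to ~10,000 features after the cap); they are
plain R and make no attempt at sparse-matrix or out-of-core scaling. The
multiblock model is supervised only. Pairwise canonical mode is not exactly
symmetric under swapping the datasets — the initialization from the
cross-covariance SVD and the per-side deflation make the asymmetry explicit,
matching the behavior observed in practice rather than hiding it. P-values
or stability measures for selected features are out of scope; the CV
criterion surfaces are exported so users can judge the flatness of the
optimum themselves.
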