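---
title: "Models and methods behind mirimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirimmune)
```

`mirimmune` implements a pipeline for studying the immune function of
colon-cancer-associated miRNAs from curated target-gene interactions: a
dual-branch neural classifier scores miRNAs for disease association, the
candidates are mapped to immune-related target genes, those genes feed a
penalized proportional-hazards prognostic model, bulk tumour expression is
deconvolved into immune-cell fractions, and the immune target genes are
tested for pathway over-representation.  This vignette explains each model,
the choices that were genuinely open, and what the synthetic benchmark does
and does not demonstrate.

## The classifier

Each miRNA is represented by the binary indicator vector of its target
genes over a fixed, recorded gene order; the encoding is binary membership
because curated interaction tables assert relations, not strengths.  Two
branches read this vector in parallel:

* a 3-layer multilayer perceptron (fully connected layers of 256, 64 and
  128 units, ReLU), which sees the whole profile at once and learns
  *global* features, each unit computing
  $\mathrm{out} = f\!\left(\sum_j w_j x_j + b\right)$;
* a 4-layer 1-D convolutional stack (256, 64, 128 and 128 filters with
  kernel sizes 5, 3, 3, 3, ReLU), which slides over the gene axis and
  learns *local* co-targeting features,
  $\mathrm{out}[i] = f\!\left(\sum_{j} w[j]\, x[i+j] + b\right)$
  (cross-correlation, valid positions only, stride 1).

A 2-layer fusion head (32 units with ReLU, then 2 units with softmax)
consumes the concatenation of the 128-length MLP output followed by the
128-length pooled CNN output and returns the class-probability pair.

Choices the architecture description leaves open, fixed here:

* **Pooling.**  The convolutional branch uses pooling layers, but their
  placement and widths are free parameters.  We apply max-pooling of widths
  8, 4 and 4 after conv layers 1–3 and global average pooling after layer
  4, which yields the fixed 128-length fusion input for any input length.
  The wide first pool collapses the long position axis right after the
  256-filter layer; positional detail at single-gene resolution carries no
  meaning under an arbitrary gene ordering, so the pyramid trades it for
  translation-tolerant local features (and keeps the layer-1/2 boundary,
  where almost all of the arithmetic lives, compact).  Pool widths are
  recorded in the parameter object and can be overridden.
* **Final activation.**  The 2-unit output layer uses softmax: the model
  makes a two-class decision.
* **Fusion order.**  MLP output first, then the pooled CNN output; the
  constant is recorded so serialized models are unambiguous.
* **Gene order.**  The canonical column order of the association matrix.
  It is biologically arbitrary but fixed at generation/load time, so runs
  are reproducible.
* **Training regime** (none is prescribed): Adam with learning rate
  1e-3, batch size 32, 100 epochs, inverse-frequency class weights to
  offset the label imbalance (e.g. 133 positives vs 500 negatives), all
  overridable through `train_config()`.  Training minimizes class-weighted
  softmax cross-entropy and is bit-reproducible under a fixed seed.
* **Regularization.**  None by default (none is prescribed); early
  stopping on the training loss is available via `early_stop_patience`.

The MLP unit sequence 256 → 64 → 128 is non-monotonic but intentional: it
is implemented exactly as specified for the reference architecture.

Both branches and the trainer are implemented twice: a pure-R reference
engine (`R/nn-core.R`) used by the gradient-check tests, and a compiled
RcppArmadillo backend used for fitting, with im2col + GEMM convolutions, a
chunked fused bias/ReLU/max-pool forward and a pooling-aware sparse
backward.  The two are verified against each other to near machine
precision on random networks, and the analytic gradients are checked
against central finite differences at differentiable points.

Baselines mirror the comparison models of the study: a dense-only deep
network (the MLP branch plus fusion head, trained identically), a
linear-kernel SVM (decision values mapped monotonically to scores), and a
k-nearest-neighbour scorer (fraction of positive labels among the k = 5
nearest profiles in Euclidean/Hamming distance).

## Evaluation and candidate ranking

`make_folds()` builds class-stratified k-fold assignments (per-fold
positive counts differ by at most one).  `auc()` is the normalized
Mann–Whitney statistic with half-credit ties; `aupr()` is average
precision, i.e. step integration with precision held right-continuous
between achieved recall levels and tied scores processed as one block.
Mean ROC/PR curves are vertical averages of the per-fold step curves on a
fixed 101-point grid.  Candidate miRNAs are ranked by descending score
with ties broken lexicographically by identifier; both a score threshold
(default 0.5) and a top-n rule are exposed, since the original candidate
cutoff is not documented.

## Survival analysis

The prognostic stage assumes proportional hazards,
$h(t \mid x) = h_0(t)\, \exp(\alpha_1 x_1 + \dots + \alpha_n x_n)$, and
maximizes the L1-penalized Cox partial likelihood over a penalty path
(glmnet), selecting the penalty by 10-fold cross-validated
partial-likelihood deviance.  Covariates are standardized internally and
coefficients reported on the original scale.  Both the deviance-minimizing
`lambda_min` and the 1-SE penalty are reported; selection defaults to
`lambda_min` (the rule used originally is not documented).  Ties in event
times use the Breslow approximation, and a Breslow cumulative baseline
hazard accompanies the coefficients.  The risk score is the linear
predictor $\sum_i \alpha_i x_i$.

Per-gene and risk-group survival curves split the cohort at the median —
the least-parameterized cut-point convention, since none is documented —
with ties going to the low group.  Curves are Kaplan–Meier product-limit
estimates and group differences use the standard two-group log-rank
chi-square with one degree of freedom.  Following the original narrative,
which counts p = 0.05 among the significant results, the significance
convention here is p ≤ 0.05.

## Immune-cell deconvolution

`deconvolve_sample()` follows the CIBERSORT recipe: restrict the mixture
to the signature genes, z-score the mixture and each signature column, fit
a linear ν-support-vector regression for ν ∈ {0.25, 0.5, 0.75}, keep the ν
with the smallest reconstruction RMSE, map the z-space coefficients back to
the original expression scale (a z-space weight w_j represents w_j / sd_j
worth of signature column j, so skipping this step would report
sd-weighted fractions), clip negatives to zero and renormalize to the
simplex.  Z-scoring makes the estimates invariant
to positive rescaling of the mixture, so any linear-scale expression input
is acceptable.  The SVR cost parameter is not part of the published
convention; we use cost = 100 so that noise-free mixtures are recovered
nearly exactly (the default cost of 1 biases weights toward zero
noticeably before renormalization), and expose it as a parameter.  The
permutation p-value of the original tool is out of scope.  No reference
signature ships with the package: real analyses supply their own signature
TSV, and the synthetic generator builds one with known ground truth.

## Enrichment

Over-representation uses the one-sided hypergeometric (Fisher) upper tail
$P(X \ge x)$ for a query of n genes against a set of K genes in a universe
of N — the standard test behind KEGG/GO bar charts — with
Benjamini–Hochberg adjustment across all sets and the top 25 records
reported by default.  Raw and adjusted p-values are both reported.  The
background universe defaults to the association-matrix gene universe and
is overridable.  Note that a fixed overlap becomes *more* significant as
the universe grows (the hypergeometric upper tail is non-increasing in N);
the property tests pin this direction down.

## The synthetic benchmark

`synth_config()` fixes the study conditions; every generated artifact is a
pure function of the configuration and a single integer seed, with named
sub-streams per stage so stages can be regenerated independently.

* **Associations.**  2000 miRNAs × 2000 genes; 133 labeled positives and
  500 labeled negatives (the real label counts); baseline targeting
  density 0.02 (a few hundred curated targets per miRNA over a genome-scale
  universe is ~1–2%); positives target a hidden 100-gene disease module at
  5× the baseline density.  A 150-gene immune list overlaps the module by
  half — large enough that immune mapping has signal, small enough that
  the lists stay distinct.
* **Survival.**  174 patients (the real cohort size); expression is
  i.i.d. standard normal on a log-like scale (the downstream Cox and SVR
  stages assume continuous input; count-level noise modelling is not the
  point of this benchmark); event times are exponential with rate
  $h_0 \exp(x^\top \beta)$, the simplest law satisfying the
  proportional-hazards form, with $h_0 = 0.1$ per time unit and uniform
  censoring tuned by root-finding so the realized censored fraction
  approximates the 30% target.
* **Mixtures.**  A 22-cell-type signature (the classic immune panel size)
  with 10 exclusive marker genes per type (markers ~Uniform(8, 12) against
  a ~Uniform(0.5, 1.5) background), symmetric Dirichlet(1) proportions,
  100 samples, additive Gaussian noise with sd 0.5 (~5% of the marker
  signal), floored at zero.
* **Gene sets.**  50 sets of 20–150 genes; one planted set shares half its
  members with the disease module.

What passing the benchmark shows: the full chain runs deterministically
end to end; the classifier detects a planted multiplicative over-targeting
signal and beats a nearest-neighbour baseline; the penalized Cox stage
recovers a sparse true support; deconvolution inverts known mixtures
within tight error; enrichment finds a planted set.  What it does not
show: performance on real curated databases (identifier harmonization,
correlated targeting, database bias), count-distributed expression, batch
effects, or miRNA sequence features — all intentionally outside the
generator.

## Problem sizes and numerical notes

The standing benchmark used by the acceptance checks trains the classifier
for 4 epochs with batch size 128 at the full 2000-gene scale: the planted
signal is strong and the checks concern ordering (classifier above chance
and above kNN), not asymptotic accuracy, so a short schedule is the
appropriate size for a reproducible benchmark.  Support recovery uses 50
replicates of a 500-patient, 50-gene cohort with effects ±1; the log-rank
level check uses 1000 null replicates of two 100-patient arms; planted-set
recovery uses 100 replicates.

Degenerate inputs are handled explicitly: single-class training labels,
all-identical values at a median split, empty queries after universe
filtering, all-zero mixtures, and constant covariates (dropped with a
warning) all raise informative errors rather than propagating NaNs.
Max-pool ties keep the earliest position; median ties go to the low
group; candidate-ranking ties are broken by identifier so all orderings
are total and reproducible.

## Known limitations

* The classifier treats the gene axis as an arbitrary but fixed sequence;
  convolutional features are therefore order-dependent in a way that has
  no biological interpretation.  This mirrors the reference architecture
  rather than endorsing it.
* `fit_lasso_cox()` assumes proportional hazards and handles neither
  time-dependent covariates nor competing risks.
* Deconvolution assumes the signature covers the cell types present;
  absent types bias fractions toward the signature's span.
* The hypergeometric test treats genes as exchangeable; no topology or
  gene-length bias correction is attempted.
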