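# mirimmune

Immune-function analysis of disease-associated miRNAs and their target
genes, built around colon cancer as the motivating disease.

miRNAs repress their target mRNAs, and a miRNA's disease relevance is
written into *which* genes it targets.  `mirimmune` turns a curated
miRNA→target-gene table into a full immune-oriented analysis:

1. **Classification.**  A dual-branch neural network scores each miRNA
   for disease association from its binary target-profile
   `x ∈ {0,1}^G`.  One branch is a 3-layer MLP (256/64/128 units,
   `out = f(Σ w_j x_j + b)`) learning global profile features; the other
   is a 4-layer 1-D CNN (256/64/128/128 filters, kernels 5/3/3/3,
   `out[i] = f(Σ_j w[j] x[i+j] + b)`) learning local co-targeting
   features along the fixed gene axis; a 2-layer softmax head
   (32 → 2 units) fuses the two 128-length branch outputs.  Training is
   class-weighted cross-entropy with Adam, reproducible under a seed.
   Comparison baselines: a dense-only deep network, a linear SVM, and a
   k-nearest-neighbour scorer.
2. **Evaluation and prediction.**  Stratified 10-fold cross-validation
   with exact AUC (Mann–Whitney) and AUPR (average precision), averaged
   ROC/PR curves, and ranking of unlabeled miRNAs into a candidate list.
3. **Immune mapping.**  Candidate miRNAs are mapped to their target-gene
   union and intersected with an immune gene list (InnateDB-style),
   yielding the headline counts: targets, immune-related targets, and
   miRNAs carrying immune targets.
4. **Prognosis.**  The immune target genes enter an L1-penalized Cox
   model `h(t|x) = h0(t)·exp(α₁x₁ + … + αₙxₙ)` with the penalty chosen by
   10-fold cross-validated deviance; selected genes and the median-split
   risk score get Kaplan–Meier curves and log-rank tests.
5. **Deconvolution.**  CIBERSORT-style ν-SVR against a cell-type
   signature matrix estimates immune-cell fractions per bulk sample,
   with mean-abundance rankings across the cohort.
6. **Enrichment.**  One-sided hypergeometric over-representation of the
   immune target genes against GMT gene-set collections, with
   Benjamini–Hochberg correction and top-25 reporting.

A synthetic-data module generates every input with planted ground truth
(an over-targeted disease gene module, known Cox coefficients, known
mixing proportions, a planted enriched set), so the whole pipeline is
testable end to end without downloading anything.

## Worked example

Score a synthetic miRNA universe, rank candidates, and map them to
immune genes:

```r
library(mirimmune)

cfg <- synth_config(n_mirna = 400, n_gene = 800, n_positive = 60,
                    n_negative = 120, disease_module_size = 50,
                    immune_set_size = 80, seed = 42)
sim <- generate_associations(cfg)

ids    <- c(sim$positive_ids, sim$negative_ids)
labels <- rep(c(1L, 0L), c(60, 120))
X      <- sim$matrix[ids, ]

folds <- make_folds(labels, k = 5, seed = 1)
cv <- cross_validate("ccnet", X, labels, folds,
                     train_cfg = train_config(epochs = 5, batch_size = 64))
cv
#> <cv_result> 5 folds: mean AUC 0.798, mean AUPR 0.703

fit    <- ccnet_train(X, labels, train_config(epochs = 5, batch_size = 64))
scores <- predict_scores(fit, sim$matrix[sim$unlabeled_ids, ])
cands  <- rank_candidates(scores, sim$unlabeled_ids, top_n = 20)
head(cands, 3)
#> # A tibble: 3 × 3
#>   mirna_id score  rank
#>   <chr>    <dbl> <int>
#> 1 mir0236  0.913     1
#> 2 mir0330  0.871     2
#> 3 mir0130  0.852     3

pairs_idx <- which(sim$matrix == 1L, arr.ind = TRUE)
pairs <- data.frame(mirna = rownames(sim$matrix)[pairs_idx[, 1]],
                    gene  = colnames(sim$matrix)[pairs_idx[, 2]])
summarize_immune(build_target_map(pairs), cands$mirna_id, sim$immune_set)
#> <immune_summary> 20 miRNAs -> 318 target genes, 39 immune-related, 19 miRNAs with immune targets
```

The cross-validated AUC of ~0.8 reflects the planted 5× over-targeting
signal; the top-ranked candidates are unlabeled miRNAs whose profiles
resemble the positive class, and about one in eight of their pooled
target genes is immune-related, matching the generator's immune/module
overlap.

The same stages run file-to-file through `run_pipeline(pipeline_config(...))`,
which writes every artifact (TSV/GMT/JSON plus a checksummed run
manifest) into an output directory, deterministically under one seed.
`vignettes/methods.Rmd` documents the models, defaults and design
decisions in detail.

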