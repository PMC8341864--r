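# sccaCC

Multi-omics molecular subtyping and classification by sparse canonical
correlation analysis.

## The problem

Cancer subtyping studies are mostly built on a single omics layer
(typically mRNA expression), which ignores heterogeneity at other levels
of gene regulation, and the resulting classifiers cannot be applied to
cohorts profiled on a different omics platform.  `sccaCC` implements an
integrative framework for two omics views of the same samples (the
canonical use case is mRNA and miRNA expression):

1. **Projection.** Both views are projected onto a shared
   low-dimensional space by sparse canonical correlation analysis, so
   that the projected coordinates are maximally correlated across
   views and each canonical vector involves only a small set of
   features.
2. **Fusion.** The projected views are blended by weighted averaging
   into a single fused representation.
3. **Subtyping.** Resampling-based consensus k-means clustering of the
   fused samples yields stable molecular subtypes and a data-driven
   cluster number.
4. **Classification.** A classifier trained on the fused coordinates
   can label new samples from *both* views, or — because the two
   projections are maximally correlated — from a *single* view alone.
   This makes single-omics public datasets classifiable with a
   multi-omics taxonomy.

The package is aimed at computational biologists who have matched
expression matrices (features × samples, delimited text) and optionally
clinical follow-up, and want subtypes plus an applicable classifier with
the statistical evaluation that normally accompanies a subtyping study
(cluster significance, cross-taxonomy association, survival
association).

## The model

Given column-matched, feature-standardized views
`A ∈ R^{D_a×n}` and `B ∈ R^{D_b×n}`, sparse CCA is computed as an
L1-penalized rank-m decomposition of the cross-product `K = A Bᵀ`
(within-view covariances treated as identity).  Each component solves

    maximize  uᵀ K v   subject to  ‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1,
                                   ‖u‖₁ ≤ c₁,  ‖v‖₁ ≤ c₂,

with `c = penalty · √D` (default penalty 0.3), by alternating exact
soft-threshold updates; `K` is then deflated by `d·u vᵀ`.  The fused
representation is

    Z = α Aᴾ + (1−α) Bᴾ,   Aᴾ = Pₐᵀ A,  Bᴾ = P_bᵀ B,   α ∈ [0,1],

with equal weight `α = 0.5` by default.  Subtypes come from consensus
k-means over subsampled runs (500 iterations, 0.9 subsampling ratio by
default) and the cluster number from the flattening point of the
consensus-CDF area curve.  Available classifiers: random forest
(1000 trees), radial SVM (cost 10), k-nearest neighbours (k = 5),
nearest centroid, and Gaussian naive Bayes.

## Worked example

Everything below runs on a simulated cohort, so it reproduces exactly:
two views (500 genes, 120 miRNAs; the miRNA view twice as noisy) of 300
samples carrying four planted subtypes on three shared latent factors.

```r
library(sccaCC)

coh <- simulate_cohort(seed = 7)          # mrna, mirna, clinical, truth
fit <- scca_cc(coh$mrna, coh$mirna,       # z-score -> sparse CCA -> fuse
               k_range = 2:6,             # -> consensus cluster -> classify
               consensus_iter = 100, seed = 42)
fit
#> multi-omics subtype model (sparse CCA fusion)
#>   views: mrna (500 features) / mirna (120 features), 300 samples
#>   120 canonical components, fusion alpha = 0.5
#>   4 subtypes (consensus k-means), classifier: rf
#>
#>  1  2  3  4
#> 69 75 86 70
```

The consensus diagnostics picked k = 4, the planted number.  Agreement
with the simulated truth and the survival signal of the subtypes:

```r
mclust::adjustedRandIndex(fit$labels$labels, coh$truth$labels$labels)
#> [1] 0.8365422
logrank_by_subtype(coh$clinical, fit$labels)
#> log-rank test: chi-square 63.477 on 3 df, p = 1.062e-13
```

(Subtype 2 was planted with hazard ratio 3, so the fitted taxonomy
separates survival strongly.)  The model classifies new samples from
both views or from one:

```r
test <- simulate_cohort(n = 150, seed = 8)         # independent cohort
both  <- predict(fit, mrna = test$mrna, mirna = test$mirna)
mrna_only <- predict(fit, mrna = test$mrna)        # single-omics input
table(both$labels, mrna_only$labels)
#>      1  2  3  4
#>   1  6  2  0  0
#>   2  6 32  5  3
#>   3  5 12 57  6
#>   4  0  7  2  7
```

Most samples receive the same label from the fused and the mRNA-only
route; disagreements concentrate in the less separated subtypes.
Finally, `variate_pair_correlations(fit$scca, coh$mrna, coh$mirna)` reports
which features each canonical component selected and how strongly the
selected mRNA/miRNA pairs correlate against a random-pair background.

## Command line

A thin wrapper over the same functions is installed as `exec/scca-cc`
(subcommands `run`, `simulate`, `fit`, `predict`), driven by the same
YAML/JSON configuration files accepted by `run_pipeline()`; every run
writes a manifest with versions, parameters, seeds and input checksums.
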