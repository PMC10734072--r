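# nmfsubtypes

Molecular subtyping of bulk gene-expression data by non-smooth NMF
consensus clustering, with cross-dataset transfer and phenotype
association.

## What it does and for whom

Transcriptome-driven patient stratification — in particular the ALS
motor-cortex subtyping design this package implements — follows one
pipeline: normalise a genes × samples count matrix, cluster the samples
with non-smooth non-negative matrix factorisation (nsNMF), extract the
disjoint gene signature that defines each cluster, transfer cluster
membership to independent cohorts with a linear discriminant model, check
the signatures with cross-validated classifiers, and test whether cluster
membership associates with clinical phenotypes. `nmfsubtypes` packages
each of those stages as a tested R function, plus a synthetic-data
generator with planted clusters so the whole pipeline can be exercised and
validated without access-restricted cohort data.

The core model factorises the non-negative expression matrix `V` as

    V ≈ W S H,   S = (1 − θ) I + (θ/k) 11ᵀ,   0 ≤ θ ≤ 1

by multiplicative Kullback–Leibler updates (θ = 0 is standard KL-NMF; the
smoothing matrix S sparsifies `W` and `H` as θ grows). The number of
clusters is chosen by consensus clustering over repeated seeded runs,
scored by the cophenetic correlation of the consensus matrix. Gene `g`'s
posterior over clusters is the row-normalised basis `p[g,·] = W[g,·]/Σ W[g,·]`,
and genes with feature score

    f_g = 1 + (1/log₂ k) Σ_j p[g,j] log₂ p[g,j]  >  median(f) + 3·MAD(f)

form the (pairwise disjoint) cluster signatures. Transfer to a new dataset
fits ridge-regularised Gaussian LDA on the shared signature genes and
reports posterior probabilities, an average-posterior matrix, and
bootstrap stability (refit on resamples, scored against the reference
assignment). Signature validation runs SMOTE-balanced, stratified 10-fold
L2 logistic regression under three multicollinearity scenarios plus a
random-gene baseline. Phenotype association uses plain Pearson chi-square
tests (no continuity correction), one-way ANCOVA with Tukey post-hoc
tests, and a Shapiro–Wilk-gated log transform.

See `vignettes/molecular-subtyping.Rmd` for the full methods account.

## Worked example

```r
library(nmfsubtypes)

# a discovery cohort with 3 planted clusters (2000 genes, 120 samples)
cfg <- synthetic_config(seed = 7)
discovery <- generate_discovery(cfg)
prep <- preprocess(discovery, n_top = 500)

scan <- consensus_cluster(prep$matrix$values, k_range = 2:6, n_runs = 20,
                          max_iter = 500, seed = 11)
scan
#> consensus_result: chosen k = 3
#>  k cophenetic silhouette degenerate_runs
#>  2  0.9971466  0.9750505               0
#>  3  1.0000000  1.0000000               0
#>  4  0.9969580  0.5917299               2
#>  5  0.9959799  0.5459898               3
#>  6  0.9923508  0.4629127               8

fit <- nsnmf_factorize(prep$matrix$values, scan$chosen_k, seed = 1)
model <- extract_informative_genes(fit)
model
#> cluster_model: 3 clusters, informative genes: 55/58/54

# transfer to an independent cohort observed on 60% of the genes
validation <- generate_validation(discovery, gene_keep_fraction = 0.6,
                                  platform_shift_sd = 0.1,
                                  n_samples = 100, seed = 3)
shared <- intersect_genes(model$informative_genes, validation)
lda <- fit_lda(prep$matrix$values[shared, ], model$sample_labels)
res <- assign_clusters(lda, vst_transform(validation)$values)
res
#> assignment_result: 100 samples
#>  1  2  3
#> 21 54 25
#> average posterior by assigned cluster:
#>         cluster
#> assigned 1 2 3
#>        1 1 0 0
#>        2 0 1 0
#>        3 0 0 1

bootstrap_stability(lda, vst_transform(validation)$values,
                    n_iterations = 200, seed = 5)
#> bootstrap_stability (200 iterations):
#>   median accuracy   1.000 (95% CI 1.000-1.000)
#>   median silhouette 0.944 (95% CI 0.936-0.952)

# phenotype association: bundled published count table
chi_square_independence(als_contingency_tables()$targetals_bulbar)
#> chi-square test of independence: X2 = 20.10, df = 2, p = 4.33e-05
```

The chosen rank equals the planted one; the unit diagonal of the average
posterior and the bootstrap accuracy of 1.000 say every validation sample
is assigned to its planted cluster with certainty — expected at this
effect size (4-fold signature over-expression). The chi-square output
reproduces the reported bulbar-onset association of the replication
cohort from its published counts.

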