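---
title: "Molecular subtyping of bulk expression data with nmfsubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular subtyping of bulk expression data with nmfsubtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfsubtypes)
```

## The problem

Sporadic amyotrophic lateral sclerosis (ALS) is clinically and molecularly
heterogeneous. One productive way to dissect that heterogeneity is to
cluster post-mortem motor-cortex bulk RNA-seq samples from people with ALS
into molecular subtypes, extract the gene signature that defines each
subtype, and then ask (i) whether the same subtypes can be recognised in
independent cohorts — other brain banks, blood, even microarray data — and
(ii) whether subtype membership associates with clinical phenotype (sex,
site of onset, *C9orf72* carrier status, ages at onset and death).

`nmfsubtypes` implements that full analysis as a reusable, tested R
pipeline. Because the cohorts such analyses are run on are
access-restricted, the package ships a synthetic-data generator that
reproduces the statistical structure the pipeline assumes, so every stage
is exercised end-to-end by the test suite, plus the published per-cluster
phenotype count tables, which are the one part of such a study that is
reproducible at the desk.

## The model

### Preprocessing

Raw counts are normalised with the median-of-ratios size-factor estimator
(`size_factors()`): the reference for each gene is its geometric mean
across samples, genes with any zero count are excluded from the reference,
and factors are rescaled to geometric mean 1. Lowly expressed genes
(default: total count < 10 across samples — the threshold is a documented
default, configurable via `min_total_count`) and non-autosomal genes
(chromosome not in 1–22) are removed with a per-gene reason ledger.
The variance-stabilising step is the size-factor-scaled
`log2(x/sf + 1)` transform; `vst_transform()` exposes a `transform` hook so
a different monotone variance-stabiliser can be plugged in. Downstream
stages only require an approximately variance-stabilised monotone
transform, which is why the simple analytic form is the default rather
than a parametric dispersion-trend fit. Pre-normalised input (e.g.
quantile-normalised log2 microarray intensities) sets
`data_kind = "normalized"` and passes through untouched.

Clustering operates on the most variable genes, ranked by the plain median
absolute deviation of the transformed rows (`select_variable_genes()`,
default 5000). The 1.4826 consistency constant is omitted because ranking
is scale-invariant; ties break lexicographically by gene ID so selection is
deterministic.

### Non-smooth NMF and consensus clustering

The clustering engine factorises the non-negative matrix `V` (genes x
samples) as `V ~ W S H` with the non-smooth NMF smoothing matrix

    S = (1 - theta) I + (theta / k) 11'

Updates are multiplicative KL-divergence steps in which the `H` update
sees the effective basis `W S` and the `W` update the effective
coefficients `S H`; ratios are floored at `1e-12` to avoid 0/0. At
`theta = 0`, `S` is the identity and the algorithm is exactly standard
KL-NMF (the test suite checks elementwise agreement with an independent
implementation at 1e-10). As `theta` grows, reconstruction mass is forced
through the smooth component and both factors become sparser; the test
suite checks that the mean Hoyer sparseness of the basis columns is
non-decreasing over `theta` in {0, 0.5, 0.9}. The default `theta = 0.5`
is a midpoint choice: the protocol this package implements does not pin
the value, so it is exposed in the configuration. Basis columns are
normalised to unit sum with a compensating rescale of `H` once at
convergence rather than every iteration: for `theta > 0` the smoothing
matrix does not commute with a per-column rescaling, so an in-loop
normalisation would perturb the reconstruction and break the guaranteed
monotone decrease of the KL loss, which we consider the more valuable
invariant.

The number of clusters is chosen by consensus clustering
(`consensus_cluster()`): for each rank `k` (2–10 by default; 100 runs of up
to 1000 iterations in the reference protocol), independently seeded
factorisations are reduced to sample connectivity matrices (two samples
connect when they share the argmax basis component) and averaged. The
cophenetic correlation between `1 - consensus` and the cophenetic distance
of its average-linkage dendrogram measures how block-like the consensus
is; the chosen rank maximises it, with ties going to the smallest `k`.
Rank selection by maximum cophenetic correlation is this package's
documented criterion; alternatives (e.g. silhouette, which is also
reported) are reasonable.

Samples are assigned by the argmax of their `H` column, ties to the lowest
index. Informative genes come from the row-normalised basis: with
`p[g, j] = W[g, j] / sum_j W[g, j]`, the entropy-based feature score

    f_g = 1 + (1 / log2 k) * sum_j p[g, j] log2 p[g, j]

is 1 for a gene loading on a single cluster and 0 for a flat gene. Genes
with `f_g > median(f) + 3 MAD(f)` (plain MAD; the multiplier is a
configuration knob) are informative and are uniquely assigned to their
argmax cluster, so the k signatures are disjoint by construction. The
cutoff is this package's deterministic reading of "extract the informative
genes"; it is deliberately robust (median/MAD) rather than
distribution-fitted.

### Cross-dataset transfer

Cluster membership transfers to an independent dataset by linear
discriminant analysis on the intersection of the discovery signature genes
with the target's genes (`intersect_genes()`, `fit_lda()`,
`assign_clusters()`). The model is Gaussian LDA: class means, pooled
within-class covariance, class-frequency priors, posteriors by softmax of
the discriminant scores. Because the number of signature genes routinely
exceeds the number of samples, the pooled covariance is
ridge-regularised with `lambda * mean(diag(Sigma)) * I` (default
`lambda = 1e-3`), which also absorbs perfectly collinear genes. The k x k
average-posterior matrix (rows = assigned cluster) summarises assignment
certainty the way such transfers are usually reported; on well-separated
synthetic data its diagonal sits above 0.8.

Stability is assessed by bootstrap (`bootstrap_stability()`, default 1000
iterations): with the one-shot assignment fixed as reference, each
iteration resamples the target with replacement, refits the LDA on the
resample under the reference labels, reassigns *all* original samples and
scores agreement (accuracy) plus the mean silhouette of the reference
labels in the refit discriminant space (Euclidean). Refit-on-resample was
chosen deliberately: scoring a fixed deterministic model on resamples
would give accuracy identically 1 and could not produce the sub-unity
stability values reported for noisy transfers. The feature space for the
silhouette (the discriminant projection) is likewise a documented package
choice. Resamples that lose a class are redrawn and counted.

Reverse validation (`reverse_validate()`) re-clusters the target from
scratch and maps de-novo clusters to the transferred labels by
maximum-overlap assignment on the contingency table (exhaustive
permutation search — optimal, and cheap at the ranks used here), reporting
per-cluster agreement fractions. A rank mismatch is handled by the best
rectangular mapping.

### Signature validation by classification

`run_scenario()` validates a signature as a case/control (or
region-vs-region) discriminator with stratified 10-fold cross-validated L2
logistic regression under three multicollinearity scenarios: all signature
genes; greedy decollinearisation per training fold (features ranked by
one-way ANOVA F against the labels, accepted when absolutely correlated
below 0.4 with everything already accepted); and the fold-stable subset
(the intersection of the per-fold selections, then a rerun). Inside every
fold, standardisation, SMOTE minority oversampling and feature selection
are fit on the training portion only; the held-out fold never leaks into
them, which the test suite verifies by checking that permuted labels give
chance-level AUC. The regularisation strength is grid-searched on a small
logarithmic grid by inner stratified CV on ROC AUC. Whether the original
protocol selected features on training folds only is not stated; the
leakage-free reading is implemented because the leaky one invalidates the
cross-validated estimates. `random_gene_baseline()` repeats the analysis
on random gene draws (optionally excluding the signature) to show the
signature, not the dimensionality, carries the signal.

### Phenotype association

`chi_square_independence()` is the plain Pearson test — no continuity
correction, expected counts from the margins, upper-tail p at
`(r-1)(c-1)` degrees of freedom. No-correction is not incidental: it is
the convention under which the published statistics bundled in
`als_contingency_tables()` reproduce exactly from their count tables.
Category-vs-complement 2 x k tables are built with `build_binary_table()`;
the limb:bulbar comparison in the microarray blood cohort is a direct
2 x 3 of the two onset rows. Twelve of the thirteen published statistics
reproduce to two decimals under these constructions; the discovery-cohort
limb-onset value (published 6.05) does not (the same construction gives
7.22), so it is bundled for completeness but excluded from the package's
reproduction checks.

Continuous phenotypes use `ancova_oneway()` (least-squares, cluster F from
the reduced-vs-full residual sum of squares — the sum-of-squares type is
not pinned by the protocol, and reduced-vs-full is the natural choice for
a single factor of interest), Tukey-Kramer post-hoc comparisons
(`tukey_hsd()`, studentized range on covariate-adjusted means; at k = 2 it
collapses to the pooled t-test), and a Shapiro-Wilk gate
(`normality_gate()`) that log-transforms non-normal variables
(`p < 0.05`). The log base is immaterial to the Shapiro-Wilk decision
(scale-free), so natural log is used; values <= 0 under a required
transform are an explicit error rather than a silent shift. Missing
phenotype values are dropped listwise and counted.

## The synthetic-data generator

`generate_discovery()` draws negative-binomial counts
(`variance = mu + alpha mu^2`) around per-gene log-normal baseline means,
multiplied by log-normal library-size factors, with `k` planted sample
clusters each over-expressing its own disjoint block of signature genes by
`2^log2_fold_change`. `generate_validation()` draws new samples from the
same cluster model on a random gene subset with an optional per-gene
multiplicative platform shift; `generate_control()` draws from the
baseline with no signature effect. All three share the gene-level model
(baselines, signature blocks, chromosome labels) deterministically from
the configuration seed, so discovery/validation/control triplets are
coherent. A cluster-conditional phenotype table (sex, onset site,
*C9orf72* status, ages, duration) is attached so the phenotype statistics
run unchanged on synthetic data.

The defaults are the package's reference study conditions: 2000 genes, 120
samples, three clusters in the 60:28:24 proportions of the motor-cortex
discovery cohort this design emulates, 50 signature genes per cluster,
dispersion 0.2, library-size log-sd 0.2, and `log2_fold_change = 2`. No
published effect-size estimate exists for the real clusters, so the
default fold change is an explicit free parameter: 4-fold marker-gene
over-expression with moderate overdispersion is a realistic "clearly
present but noisy" signature for bulk cortex data. The phenotype model's
defaults mirror the published per-cluster demographics (e.g. *C9orf72*
carriers concentrated in cluster one, later onset in cluster two).

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: batch and extraction effects beyond a
per-gene platform shift, correlated gene modules unrelated to the planted
clusters, gradual (non-block) signatures, mixed or outlying samples,
GC/length biases, and real microarray noise. Recovery results on this
generator are a correctness check of the machinery, not an effect-size
claim about cortex data.

## Numerical choices and scale

- Multiplicative-update ratios and denominators are floored at `1e-12`.
- Convergence: relative KL change below `tol` (default `1e-5`) or
  `max_iter`.
- Initialisation: i.i.d. Uniform(0, 1) scaled by `mean(V)`; per-run seeds
  are derived deterministically from the master seed, so every consensus
  run is bit-reproducible.
- Ties: argmax assignments take the lowest index; MAD ranking breaks ties
  lexicographically.
- Degenerate runs (an empty cluster) are kept and counted, not discarded.
- The test suite and the acceptance script run the reference conditions at
  reduced size — 500 top-MAD genes, ranks 2–6, 20 consensus runs of at
  most 500 iterations, 1000 bootstrap iterations — which this package
  treats as its standard demonstration scale; the published protocol's
  5000 genes / 100 runs / 1000 iterations are reached by changing the
  configuration only.

## Worked example

```{r example, eval = FALSE}
library(nmfsubtypes)

cfg <- synthetic_config(seed = 7)
discovery <- generate_discovery(cfg)
prep <- preprocess(discovery, n_top = 500)

scan <- consensus_cluster(prep$matrix$values, k_range = 2:6, n_runs = 20,
                          max_iter = 500, seed = 11)
scan$chosen_k                       # 3

fit <- nsnmf_factorize(prep$matrix$values, scan$chosen_k, seed = 1)
model <- extract_informative_genes(fit)
lengths(model$informative_genes)    # disjoint signatures per cluster

validation <- generate_validation(discovery, gene_keep_fraction = 0.6,
                                  platform_shift_sd = 0.1,
                                  n_samples = 100, seed = 3)
shared <- intersect_genes(model$informative_genes, validation)
lda <- fit_lda(prep$matrix$values[shared, ], model$sample_labels)
res <- assign_clusters(lda, vst_transform(validation)$values)
round(res$avg_posterior, 2)

boot <- bootstrap_stability(lda, vst_transform(validation)$values,
                            n_iterations = 1000, seed = 5)
boot

chi_square_independence(als_contingency_tables()$targetals_bulbar)
```

## Known limitations

- The variance-stabilising transform is an analytic stand-in, not a
  dispersion-trend fit; columns with extreme library sizes are handled by
  the size factors alone.
- nsNMF is run CPU-single-threaded; at full protocol scale (5000 genes,
  100 runs, nine ranks) a consensus scan is an overnight job, not an
  interactive one.
- The classifier framework is binary by contract (case/control,
  region-vs-region), matching its intended uses.
- Harmonising microarray intensities with RNA-seq transforms is the
  caller's responsibility (`data_kind = "normalized"` passes intensities
  through unchanged).
- The bundled published tables reproduce the reported chi-square values
  except the discovery-cohort limb-onset statistic, which is documented
  above.
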