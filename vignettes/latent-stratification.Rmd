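---
title: "Deep-latent stratification of registry cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-latent stratification of registry cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

latentstrat stratifies registry-style case-control cohorts in three movements:
a beta-variational autoencoder compresses mixed clinical features into a
latent space; consensus k-means with clusterability and cluster-number
significance testing partitions that space into subgroups; and a one-vs-rest
regression framework maps clinical, polygenic-score (PGS) and rare-variant
burden signal onto the subgroups. This vignette explains the models, the
tunable parameters, the numerical choices, and the limits of what the
package's synthetic cohorts can demonstrate.

## The embedding model

Each individual is a row of mixed features: binary diagnosis indicators,
categorical codes, contact counts and continuous measures, with missing
entries. Preprocessing (`fit_transform()`) z-scores continuous and count
features (counts are treated as continuous inputs, because the model defines
exactly two reconstruction families: squared error for continuous and
cross-entropy for categorical data) and one-hot encodes binary and
categorical features. A missing continuous entry is stored as 0 — the
post-normalization mean — and a missing categorical entry as an all-zero
one-hot group; both are flagged in a missingness mask. When a train/test
split is present (hyperparameter tuning), z-moments come from the training
subset only; full-pipeline runs with no held-out evaluation fit them on all
individuals.

The encoder and decoder are fully connected networks with LeakyReLU
activations, batch normalization and dropout, linked through a Gaussian
latent layer by the reparameterization trick. The loss is

$$L = E_{cat} + E_{con} + \beta_t \cdot KLD,$$

where $E_{cat}$ is the masked cross-entropy over the categorical softmax
heads, $E_{con}$ the masked squared error over the continuous heads, and

$$KLD = -\frac{1}{2N} \sum_{i=1}^{N}\sum_{j=1}^{J}
  \left(1 + \ln\sigma_{ij}^2 - \mu_{ij}^2 - \sigma_{ij}^2\right)$$

the divergence of the encoder posterior from the standard-normal prior
($N$ the batch size, $J$ the latent width). Masked entries are zeroed at the
encoder input and excluded from both loss terms, so they contribute nothing
to gradients; the stored placeholder value of a missing entry is provably
inert (this is unit-tested by scribbling over placeholders and comparing
losses, gradients and latent means bit for bit). $E_{cat}$ and $E_{con}$ are
each normalized by (number of features of that family x batch size), which
keeps the loss identity $L = E_{cat} + E_{con} + \beta_t KLD$ exact at every
logged epoch.

Two training schedules stabilize optimization. KLD warm-up holds
$\beta_t = 0$ until `warmup_start` (default epoch 80), then raises it
linearly — the simplest monotone ramp consistent with an "incrementally
raised" weight — to its final value at `warmup_end` (default 150; final
$\beta$ default 0.001). Batch dilation multiplies the mini-batch size by 1.5
at epochs 50, 100 and 150 (rounding to the nearest integer, minimum 2, a
guard the schedule itself does not otherwise imply). Defaults follow the
reference configuration: one hidden layer of 600 units, 40 latent
dimensions, base batch 64, dropout 0.2, 300 epochs. The optimizer is Adam;
its learning rate (default 1e-4) and the LeakyReLU slope (0.01) are exposed
in `vae_config()` as package defaults, not asserted reference values. The
whole network is implemented in-package with explicit matrix forward and
backward passes, verified against finite-difference gradients in both
batch-statistics and running-statistics modes.

Determinism policy: one master seed derives per-stage seeds (initialization,
shuffling, latent noise, consensus runs) through a fixed integer scramble
(`derive_seed()`), so identical configuration and seed reproduce outputs
byte for byte, and partial reruns of one stage do not perturb another.

### Evaluation, tuning, stability, importance

`evaluate_vae()` scores reconstruction as (a) mean cosine similarity between
each sample's observed continuous sub-vector and its reconstruction (samples
with no observed continuous entries are skipped and counted) and (b) the
fraction of observed categorical entries whose argmax reconstruction matches
the truth. "Test log-likelihood" is the negative total loss on the test set:
the model defines no separate likelihood, so the negative evidence bound is
the only likelihood-like quantity available. `grid_search()` ranks
configurations by the unweighted mean of five per-metric ranks (train/test
cosine, train/test match, test log-likelihood), ties broken toward fewer
parameters — the aggregate is deliberately simple because no canonical
formula exists. `stability_select()` retrains each candidate (default 10
times) and compares latent embeddings through the mean absolute difference
of sample-pair cosine similarities over a fixed subsample of 10,000 pairs;
cosine similarities are rotation-invariant, so relabelings or rotations of
an identical embedding score a difference of zero.

`feature_importance()` perturbs one feature at a time to its missing
representation, re-encodes, and scores the feature by the per-sample sum of
absolute latent changes, averaged across samples (a sum aggregation is
available by flag; the mean is the default because it is invariant to cohort
size).

## Clustering the latent space

`hopkins_statistic()` measures clusterability as
$H = \sum w / (\sum u + \sum w)$, with $w$ nearest-neighbour distances from
sampled real points to the remaining real points and $u$ nearest-neighbour
distances from uniform points in the data's bounding box to the real points.
Under spatial randomness $H \sim Beta(m, m)$, mean 0.5; this package fixes
the convention "low = clustered" and always reports the complement as well,
because both orientations circulate in the literature.

`consensus_cluster()` runs k-means (Lloyd iterations from k-means++ seeding,
best of `n_init` restarts by inertia) repeatedly — 100 runs by default —
varying only the seed, accumulates the co-clustering frequency matrix C, and
derives the final assignment by reapplying k-means to the rows of C
(Euclidean metric, the literal reading of "recluster the consensus matrix").
An n x n matrix is quadratic in memory, so cohorts beyond `max_n` rows
require explicit opt-in. Stability is summarized by the median pairwise
adjusted Rand index (ARI) across runs; the in-package ARI is tested against
an exhaustive pair-counting oracle and an independent implementation.

Choosing k uses two instruments. `validity_panel()` evaluates eight indices
(mean silhouette width, Calinski-Harabasz, Davies-Bouldin, Dunn, gap
statistic with the first-SE-max rule, Hartigan's <= 10 rule, Ball-Hall
largest drop, C-index), each voting for its best k; the majority wins, ties
toward smaller k. The panel replaces a 26-index battery with a defined,
documented subset — eight standard indices spanning the main index families
are proportionate, and the panel is configurable. A `weak_structure` flag is
raised when even the best mean silhouette is below 0.25 (the conventional
"no substantial structure" boundary). `mc_reference_significance()` tests
whether the consensus at a given k is stronger than expected under
homogeneity: the statistic is PAC, the proportion of off-diagonal consensus
entries inside the ambiguity window (0.1, 0.9); the null reference is a
multivariate normal matching the data's mean and principal-component
eigen-spectrum (eigenvalues floored at 1e-8 against singularity); the
p-value is the add-one estimator $(1 + \#\{PAC_{null} \le PAC_{real}\}) /
(n_{null} + 1)$, so with 25 nulls the smallest attainable p is 1/26. The
consensus runs inside this test use a single k-means start each: run-to-run
seeding variability is precisely the signal PAC measures, and multi-restart
runs would collapse it on null data and drain power. Monte-Carlo
consensus-significance methodology also comes in a relative-cluster-stability
variant; only the PAC core is implemented here.

## Genetic signal

`normalize_pgs()` standardizes each polygenic score against the control
population: subtract the control mean, divide by the control sample SD
(n - 1 denominator, the convention of standard statistical software), making
control moments exactly (0, 1) and the map idempotent.

`ingest_vcf_burden()` consumes a biallelic, annotated VCF carrying CADD, AF
and GENE in INFO, retains records with CADD > 15 and AF < 1% — both strict,
read literally, and unit-tested at the exact boundaries — and accumulates
each individual's 0/1/2 genotype dosage into per-gene alternate-allele
counts (missing genotypes contribute 0). Multiallelic records are rejected
by position rather than silently split, and each record carries exactly one
gene annotation to avoid double counting. Whether allele frequencies are
cohort-internal or reference-panel values is the annotator's decision; the
package does not recompute them. `aggregate_genesets()` sums counts over
named gene sets (absent genes contribute zero and are logged), preserving
subset monotonicity — a core set contained in a broader set can never exceed
its burden. The shipped gene-set files under `inst/extdata/` are synthetic
placeholders (named accordingly); real analyses must supply the actual
membership lists from the source publications' supplements. Individuals
without exome data should be excluded before burden analysis; cluster-level
summaries report the subset size.

## Enrichment testing

`enrichment_scan()` compares each cluster against the rest combined, for
every outcome, with the family-matched model: logistic regression (effect:
odds ratio) for binary outcomes, ordinary least squares (effect: beta, plus
the standardized average — the mean of the cohort-z-scored outcome within
the cluster) for continuous outcomes, and Poisson regression (effect: rate
ratio) for counts, switching to a maximum-likelihood negative binomial when
the Cameron-Trivedi auxiliary-regression dispersion test rejects at 0.05.
The dispersion test regresses $((y-\hat\mu)^2 - y)/\hat\mu$ on $\hat\mu$
without intercept and tests the slope one-sidedly; it is the standard
overdispersion diagnostic in the ecosystem these models come from.
Zero-inflated models are not provided. All models adjust for the configured
covariates (sex, age, cohort-wave indicator, 10 genetic PCs by default);
p-values are Wald. Binary and count comparisons with fewer than 5 events in
either the cluster or the remainder are excluded (the threshold's side is
configurable; requiring both sides is the default because a handful of
events on either side makes the GLM fragile). Perfect separation and
non-convergence are flagged as non-estimable instead of reporting an
arbitrarily large effect. Multiplicity is controlled within explicit
analysis families (clinical, PGS, rare-variant) by Bonferroni and
Benjamini-Hochberg side by side, with significance stars on each scale.
Whether standardized averages should z-score within cases only or the whole
analysis population is genuinely ambiguous; the whole-population convention
is the default and the alternative is a flag.

## The synthetic cohort generator

Restricted registry and exome data cannot ship with a package, so
`generate_cohort()` plants a known mixture: k clusters (equal mixing by
default), with binary features drawn from cluster-specific Bernoulli rates,
counts from negative binomial with cluster-specific means (size = Inf gives
Poisson, so both branches of the count-model switch are reachable),
continuous features from unit-variance Gaussians whose cluster means differ
by `separation` (in within-cluster SD units, the scale that makes the
parameter interpretable), and categoricals from cluster-tilted multinomials.
Missingness is uniform missing-at-random — the simplest mechanism compatible
with the imputation scheme, since registry missingness is not characterized.
Covariates are generated independently of cluster membership. PGS columns
are Normal(shift, 1) with per-cluster shifts; rare-allele counts are Poisson
with per-gene baseline rates modulated by per-cluster gene-set multipliers,
and can be materialized as an annotated VCF whose genotypes reproduce the
counts exactly and which includes decoy records at and beyond the CADD/AF
boundaries.

What the generator does not emulate — and what passing tests therefore do
not show about real data: within-cluster feature correlation (features are
independent given the cluster), longitudinal diagnosis trajectories, ICD
code hierarchies, informative missingness, and linkage disequilibrium
underlying real PGS construction.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down designs chosen as
realistic smallest sizes at which each property is identifiable: cohort
recovery uses 2,000 individuals, 65 features, a 64-unit single hidden layer,
10 latent dimensions and 30 epochs (learning rate 5e-3 at this scale);
calibration checks use 200-500 simulation replicates; the cluster-number
significance calibration uses 200 null datasets of 60 x 4 with 25 references
each. Batch-normalization uses epsilon 1e-5 and momentum 0.1; encoder
log-variances are clamped to [-10, 10]; k-means empty clusters trigger
internal re-seeding before erroring; categorical probabilities are floored
at 1e-12 inside logarithms. Two-stage runs (`run_two_stage()`) stamp every
artifact with the configuration hash and master seed, so identical runs are
byte-identical and any drift is detectable.

## Known limitations

The panel of validity indices, the PAC window, the warm-up shape and the
minimum-event side are defensible defaults, not uniquely determined choices;
all are configurable. The negative-binomial fallback can fail to converge on
degenerate outcomes, in which case the Poisson fit is reported with a
warning flag. The Hopkins statistic's bounding-box uniform reference is
sensitive to outliers in the embedding. Consensus matrices are dense n x n
objects; very large cohorts need the documented opt-in and memory to match.
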