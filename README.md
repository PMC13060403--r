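# latentstrat

Deep-latent stratification of registry-based case-control cohorts, with
genetic follow-up. The package is aimed at biostatisticians and psychiatric
epidemiologists who want to (1) compress mixed clinical features — binary
diagnoses, categorical codes, contact counts, continuous measures, with
missingness — into a latent space with a beta-variational autoencoder,
(2) partition that space into robust subgroups by consensus k-means with
clusterability (Hopkins) and Monte-Carlo cluster-number significance
testing, and (3) ask whether common-variant (polygenic score) and
rare-variant (CADD-filtered gene-set burden) signal is unevenly distributed
across the subgroups through one-vs-rest regression enrichment.

## The model in brief

The embedding minimizes

    L = E_cat + E_con + beta_t * KLD,

where `E_cat` is masked cross-entropy over per-feature softmax heads,
`E_con` masked squared error over continuous heads, and

    KLD = -(1/2N) * sum_i sum_j (1 + ln sigma_ij^2 - mu_ij^2 - sigma_ij^2)

the Kullback-Leibler divergence of the Gaussian encoder posterior from the
standard-normal prior (N = batch size, J latent dimensions). `beta_t`
follows a warm-up schedule (0 until epoch 80, linear ramp to its final
value, default 0.001, at epoch 150) and the mini-batch size dilates by 1.5x
at epochs 50/100/150. Missing entries are masked out of the loss and the
gradients entirely. Subgrouping uses k-means run repeatedly on the encoder
means, a co-clustering consensus matrix, the PAC statistic against
eigen-structure-matched multivariate-normal nulls for choosing k, and the
adjusted Rand index for stability. Enrichment uses logistic / linear /
Poisson models (negative binomial when a dispersion test detects
overdispersion), covariate adjustment, a minimum-event filter, and
Bonferroni + Benjamini-Hochberg correction within declared analysis
families.

Because the registry and exome data this design targets are
access-restricted, the package ships a first-class synthetic-cohort
generator (`cohort_spec()`, `generate_cohort()`, `generate_pgs()`,
`generate_variant_data()`) that plants known cluster structure, PGS shifts
and gene-set burden multipliers, so every stage is testable end to end.

## Worked example

```r
library(latentstrat)

spec <- cohort_spec(n_individuals = 600, k_true = 3, separation = 3,
                    case_rate_by_cluster = c(0.15, 0.7, 0.7),
                    pgs_traits = list(SCZ = c(0.3, 0, 0)),
                    missing_rate = 0.1, seed = 7)
cohort <- generate_cohort(spec)
pm <- fit_transform(cohort$table, cohort$metadata)
pm
#> preprocessed_matrix: 600 individuals x 95 encoded columns
#>   (65 features; 600 train / 0 test; 9.9% missing)

model <- train_vae(pm,
  vae_config(hidden_layers = 64, latent_dim = 10, learning_rate = 5e-3),
  training_schedule(total_epochs = 30, warmup_start = 10, warmup_end = 20,
                    dilation_epochs = c(10, 20), seed = 1))
mu <- encode(model, pm)

hopkins_statistic(mu, seed = 2)$H
#> [1] 0.2726518                      # well below 0.5: clustered latent space

cc <- consensus_cluster(mu, k = 3, runs = 100, seed = 3)
adjusted_rand_index(cc$assignment, cohort$truth$cluster)
#> [1] 1                              # planted clusters recovered exactly

pgs <- normalize_pgs(generate_pgs(spec, cohort$truth),
                     cohort$table$case_status == "control")
enrichment_scan(pgs["SCZ"], "continuous", cc$assignment,
                covariates = cohort$table[, covariate_names()],
                family_label = "pgs")[,
  c("outcome", "cluster", "effect", "std_avg", "p_bonf", "stars_bonf")]
#>   outcome cluster     effect     std_avg      p_bonf stars_bonf
#> 1     SCZ       1 -0.0740621 -0.05114811 1.000000000
#> 2     SCZ       2  0.2668100  0.17810020 0.006177098         **
#> 3     SCZ       3 -0.2021727 -0.14132628 0.066472191
```

The planted +0.3 SD polygenic-score shift lands in consensus cluster 2
(cluster labels are arbitrary up to permutation): the linear one-vs-rest
beta is 0.27 with a Bonferroni-significant p, and the standardized average
(mean cohort-z-scored PGS inside the cluster) is 0.18. The Hopkins value
near 0.27 flags latent clustering under this package's low-means-clustered
convention.

The end-to-end orchestration — stage 1 on the full cohort, stage 2 retrained
on cases only, with artifacts stamped by config hash and seed — lives in
`pipeline_config()` / `run_two_stage()` / `report()`.

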