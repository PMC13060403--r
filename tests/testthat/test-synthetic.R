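test_that("generated cohort honours the requested shapes and label contract", {
  spec <- cohort_spec(n_individuals = 1000L, k_true = 3L, separation = 2,
                      n_binary = 20L, n_count = 20L, n_continuous = 20L,
                      n_categorical = 5L, seed = 1L)
  g <- generate_cohort(spec)
  expect_equal(nrow(g$table), 1000L)
  expect_equal(nrow(g$metadata), 65L)
  expect_setequal(setdiff(names(g$table), c("id", "case_status",
                                            covariate_names())),
                  g$metadata$feature)
  expect_true(all(g$truth$cluster %in% 1:3))
  expect_true(all(tabulate(g$truth$cluster, 3) > 0))
  expect_true(all(g$table$case_status %in% c("case", "control")))
})

test_that("spec validation rejects bad fields by name", {
  expect_error(cohort_spec(n_individuals = 0), "n_individuals")
  expect_error(cohort_spec(n_individuals = 2, k_true = 5), "k_true")
  expect_error(cohort_spec(n_individuals = 10, case_fraction = 1.2),
               "case_fraction")
  expect_error(cohort_spec(n_individuals = 10, missing_rate = 1),
               "missing_rate")
  expect_error(cohort_spec(n_individuals = 10, n_binary = 0, n_count = 0,
                           n_continuous = 0, n_categorical = 0),
               "sum")
  expect_error(cohort_spec(n_individuals = 10, mixing = c(0.5, 0.2, 0.2)),
               "mixing")
})

test_that("generation is deterministic given the seed and differs across seeds", {
  a <- generate_cohort(tiny_spec(seed = 5L))
  b <- generate_cohort(tiny_spec(seed = 5L))
  c <- generate_cohort(tiny_spec(seed = 6L))
  expect_identical(a, b)
  expect_false(identical(a$table, c$table))
})

test_that("observed missingness rate matches the requested rate", {
  spec <- tiny_spec(seed = 9L, n_individuals = 5000L, missing_rate = 0.2)
  g <- generate_cohort(spec)
  fm <- as.matrix(g$table[, g$metadata$feature])
  n_entries <- length(fm)
  ci <- stats::qbinom(c(0.005, 0.995), n_entries, 0.2) / n_entries
  expect_gte(mean(is.na(fm)), ci[1])
  expect_lte(mean(is.na(fm)), ci[2])
})

test_that("separation = 0 plants no recoverable structure (ARI at chance)", {
  spec <- tiny_spec(seed = 12L, n_individuals = 200L, separation = 0,
                    missing_rate = 0)
  g <- generate_cohort(spec)
  x <- as.matrix(g$table[, g$metadata$feature])
  km <- kmeans_fit(scale(x), 2L, seed = 3L)
  ari <- adjusted_rand_index(km$cluster, g$truth$cluster)
  # permutation null distribution of the ARI for these label margins
  null <- with_seed(7L, replicate(500, adjusted_rand_index(
    sample(km$cluster), g$truth$cluster)))
  expect_gte(mean(abs(null) >= abs(ari)), 0.05)
})

test_that("PGS generation recovers the planted cluster shift", {
  spec <- tiny_spec(seed = 15L, n_individuals = 20000L, k_true = 2L,
                    n_binary = 1L, n_count = 0L, n_continuous = 1L,
                    n_categorical = 0L,
                    pgs_traits = list(SCZ = c(0.2, 0), NULLTRAIT = c(0, 0)))
  g <- generate_cohort(spec)
  pgs <- generate_pgs(spec, g$truth)
  ind <- as.integer(g$truth$cluster == 1L)
  fit <- summary(stats::lm(pgs$SCZ ~ ind))$coefficients
  ci <- fit["ind", "Estimate"] + c(-2, 2) * fit["ind", "Std. Error"]
  expect_gte(0.2, ci[1])
  expect_lte(0.2, ci[2])
  # no-shift trait: cluster difference is indistinguishable from zero
  fit0 <- summary(stats::lm(pgs$NULLTRAIT ~ ind))$coefficients
  expect_gt(fit0["ind", "Pr(>|t|)"], 0.001)
  expect_identical(generate_pgs(spec, g$truth), pgs)
})

test_that("variant generation round-trips through VCF exactly", {
  spec <- gene_fixture(seed = 21L, mult = c(2, 1))
  g <- generate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".vcf")
  vd <- generate_variant_data(spec, g$truth, format = "vcf", path = path)
  ingested <- ingest_vcf_burden(path)
  expect_identical(
    unname(ingested[rownames(vd$counts), colnames(vd$counts)]),
    unname(vd$counts))
  # matrix format agrees with the VCF ground truth
  m <- generate_variant_data(spec, g$truth, format = "matrix")
  expect_identical(m, vd$counts)
  expect_error(generate_variant_data(tiny_spec(), g$truth), "gene_panel")
})

test_that("neutral multipliers leave per-cluster burden flat, planted ones recover", {
  # multiplier 1 everywhere: difference consistent with Poisson noise
  spec0 <- gene_fixture(seed = 30L, n = 2000L, mult = c(1, 1))
  g0 <- generate_cohort(spec0)
  m0 <- generate_variant_data(spec0, g0$truth, format = "matrix")
  tot <- rowSums(m0)
  p <- summary(stats::glm(tot ~ factor(g0$truth$cluster),
                          family = stats::poisson()))$coefficients
  expect_gt(p[2, "Pr(>|z|)"], 0.001)
  # multiplier 2 on the core set for cluster 1: Poisson RR recovers 2
  spec2 <- gene_fixture(seed = 31L, n = 4000L, mult = c(2, 1))
  g2 <- generate_cohort(spec2)
  m2 <- generate_variant_data(spec2, g2$truth, format = "matrix")
  core <- aggregate_genesets(m2, gene_set("core", c("SETD1A", "TRIO")))$core
  ind <- as.integer(g2$truth$cluster == 1L)
  fit <- summary(stats::glm(core ~ ind, family = stats::poisson()))$coefficients
  ci <- exp(fit["ind", "Estimate"] + c(-2, 2) * fit["ind", "Std. Error"])
  expect_gte(2, ci[1])
  expect_lte(2, ci[2])
})
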