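test_that("one-vs-rest indicators partition the cohort", {
  a <- c(1, 1, 2, 3)
  expect_equal(one_vs_rest_indicator(a, 1), c(1L, 1L, 0L, 0L))
  total <- Reduce(`+`, lapply(unique(a), one_vs_rest_indicator,
                              assignment = a))
  expect_equal(total, rep(1L, 4))
  expect_error(one_vs_rest_indicator(a, 9), "empty")
})

test_that("event filter applies the <5 boundary on both sides", {
  ind <- rep(c(1L, 0L), each = 50)
  y4 <- c(rep(1, 4), rep(0, 46), rep(1, 20), rep(0, 30))
  y5 <- c(rep(1, 5), rep(0, 45), rep(1, 20), rep(0, 30))
  expect_false(event_filter(y4, ind)$include)
  expect_true(event_filter(y5, ind)$include)
  # remainder side also counts by default
  y_out <- c(rep(1, 20), rep(0, 30), rep(1, 4), rep(0, 46))
  expect_false(event_filter(y_out, ind)$include)
  expect_true(event_filter(y_out, ind, both_sides = FALSE)$include)
})

test_that("logistic OR matches the 2x2 closed form; separation is flagged", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  ind <- rep(c(1L, 0L), each = 100)
  r <- test_binary(y, ind)
  expect_equal(r$effect, 27 / 7, tolerance = 1e-6)
  expect_false(r$excluded)
  sep <- test_binary(ind, ind)
  expect_true(sep$excluded)
  expect_match(sep$reason, "separation")
})

test_that("Poisson RR matches the ratio of means; NB branch engages under overdispersion", {
  with_seed(53L, {
    ind <- rep(c(1L, 0L), each = 400)
    y <- c(rpois(400, 4), rpois(400, 2))
    r <- test_count(y, ind)
    expect_equal(r$effect, mean(y[ind == 1]) / mean(y[ind == 0]),
                 tolerance = 1e-6)
    expect_equal(r$family, "poisson")
    # strongly overdispersed counts switch to negative binomial
    y_nb <- c(rnbinom(400, size = 0.5, mu = 4), rnbinom(400, size = 0.5, mu = 2))
    r_nb <- test_count(y_nb, ind)
    expect_equal(r_nb$family, "negbin")
    ci <- exp(log(r_nb$effect) + c(-3, 3) * 0.25)
    expect_true(2 >= ci[1] && 2 <= ci[2])
  })
})

test_that("dispersion test is calibrated under Poisson and powered under NB", {
  with_seed(57L, {
    ind <- rep(c(1L, 0L), each = 250)
    typeI <- mean(replicate(300, {
      y <- rpois(500, exp(0.5 + 0.3 * ind))
      dispersion_test(y, ind)$p_value < 0.05
    }))
    expect_lt(abs(typeI - 0.05), 0.035)
    ind2 <- rep(c(1L, 0L), each = 1000)
    power <- mean(replicate(100, {
      y <- rnbinom(2000, size = 0.5, mu = exp(0.5 + 0.3 * ind2))
      dispersion_test(y, ind2)$p_value < 0.05
    }))
    expect_gt(power, 0.9)
    expect_false(dispersion_test(rep(0, 100), rep(c(1L, 0L), 50))$defined)
  })
})

test_that("linear test: closed-form beta and standardized average anchors", {
  with_seed(59L, {
    ind <- rep(c(1L, 0L), each = 150)
    y <- rnorm(300) + 0.5 * ind
    r <- test_continuous(y, ind)
    expect_equal(r$effect, mean(y[ind == 1]) - mean(y[ind == 0]),
                 tolerance = 1e-9)
    # cluster = whole cohort: standardized average is exactly 0
    r_all <- test_continuous(y, rep(1L, 300), covariates = NULL)
    expect_equal(r_all$std_avg, 0, tolerance = 1e-12)
    expect_error(test_continuous(rep(1, 10), rep(c(1L, 0L), 5)), "variance")
  })
})

test_that("multiplicity adjustment matches the hand-worked step-up example", {
  adj <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$p_bonferroni, c(0.04, 0.08, 0.12, 0.16))
  expect_equal(adj$q_bh, rep(0.04, 4))
  one <- adjust_pvalues(0.01)
  expect_equal(one$p_bonferroni, 0.01)
  expect_equal(one$q_bh, 0.01)
  capped <- adjust_pvalues(rep(0.9, 5))
  expect_true(all(capped$p_bonferroni <= 1))
  # NA p-values excluded from the family size
  with_na <- adjust_pvalues(c(0.01, NA, 0.02))
  expect_equal(with_na$p_bonferroni[1], 0.02)
  expect_true(is.na(with_na$p_bonferroni[2]))
  # ordering invariant: bonferroni >= BH q >= raw p
  with_seed(61L, {
    p <- runif(50)
    a <- adjust_pvalues(p)
    expect_true(all(a$p_bonferroni >= a$q_bh - 1e-12))
    expect_true(all(a$q_bh >= a$p - 1e-12))
  })
})

test_that("enrichment scan covers every outcome x cluster pair exactly once", {
  with_seed(63L, {
    n <- 240
    assignment <- sample(1:3, n, TRUE)
    outcomes <- data.frame(
      dx = rbinom(n, 1, 0.3),
      contacts = rpois(n, 2),
      pgs = rnorm(n),
      rare_dx = c(rep(1, 3), rep(0, n - 3)))  # fails the event filter
    covars <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 18, 45))
    res <- enrichment_scan(outcomes,
                           c("binary", "count", "continuous", "binary"),
                           assignment, covars, family_label = "clinical")
    expect_equal(nrow(res), 4 * 3)
    expect_equal(sum(res$excluded & res$outcome == "rare_dx"), 3L)
    kept <- res[!res$excluded, ]
    expect_true(all(kept$p_bonf >= kept$p - 1e-12))
    expect_true(all(kept$q_fdr <= kept$p_bonf + 1e-12))
    expect_true(all(res$family[res$outcome == "pgs"] == "linear"))
    expect_error(enrichment_scan(outcomes[1:10, ], rep("binary", 4),
                                 assignment), "misaligned")
  })
})

test_that("null outcomes give uniform p-values and Bonferroni controls FWER", {
  with_seed(67L, {
    n <- 300
    assignment <- rep(1:2, each = n / 2)
    pvals <- replicate(400, {
      y <- rbinom(n, 1, 0.3)
      test_binary(y, one_vs_rest_indicator(assignment, 1))$p
    })
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
    # FWER under Bonferroni across a small family
    fwer <- mean(replicate(200, {
      outcomes <- data.frame(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.4),
                             c = rnorm(n), d = rpois(n, 1.5))
      res <- enrichment_scan(outcomes,
                             c("binary", "binary", "continuous", "count"),
                             assignment)
      any(res$p_bonf < 0.05, na.rm = TRUE)
    }))
    expect_lte(fwer, 0.1)
  })
})

test_that("cluster composition reproduces the printed-count arithmetic", {
  # 10632 / 11046 controls in one cluster -> 96.3%; 7710 / 11046 cases -> 69.8%
  status <- c(rep("control", 11046), rep("case", 11046))
  assignment <- c(rep("A", 10632), rep("B", 414),
                  rep("A", 3336), rep("B", 7710))
  comp <- cluster_composition(assignment, status)
  a <- comp[comp$cluster == "A", ]
  b <- comp[comp$cluster == "B", ]
  expect_equal(a$pct_controls_label, "96.3%")
  expect_equal(b$pct_cases_label, "69.8%")
  expect_equal(a$pct_cases_label, "30.2%")
  expect_equal(a$n_controls, 10632)
  expect_equal(a$n_cases, 3336)
  # empty-cluster degenerate: a level absent from the assignment
  comp0 <- cluster_composition(c("A", "A"), c("case", "control"))
  expect_equal(comp0$n, 2)
})
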