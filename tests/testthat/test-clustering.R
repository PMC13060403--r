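test_that("Hopkins statistic separates clustered from uniform data", {
  bl <- blob_data(n_per = 80L, sep = 8, p = 2L, seed = 3L)
  h_blobs <- hopkins_statistic(bl$x, m = 50L, seed = 4L)
  expect_lt(h_blobs$H, 0.2)
  expect_equal(h_blobs$complement, 1 - h_blobs$H)
  # near-duplicate points (two stacks of copies) drive H towards 0
  dup <- rbind(matrix(rep(c(0, 0), 25), ncol = 2, byrow = TRUE),
               matrix(rep(c(10, 10), 25), ncol = 2, byrow = TRUE)) +
    matrix(rnorm(100, sd = 1e-6), ncol = 2)
  expect_lt(hopkins_statistic(dup, m = 10L, seed = 1L)$H, 0.01)
  expect_error(hopkins_statistic(bl$x, m = nrow(bl$x), seed = 1L), "m must")
  expect_error(hopkins_statistic(matrix(1, 5, 2), m = 2L), "bounding box")
})

test_that("Hopkins null distribution is centred at 0.5 under uniformity", {
  m <- 10L
  hs <- with_seed(17L, replicate(200, {
    x <- matrix(runif(60 * 2), 60, 2)
    hopkins_statistic(x, m = m, seed = sample.int(1e6, 1))$H
  }))
  # H ~ Beta(m, m) under spatial randomness: mean 0.5, known SE
  se <- sqrt(1 / (4 * (2 * m + 1)) / 200)
  expect_lt(abs(mean(hs) - 0.5), 3 * se)
})

test_that("k-means handles the closed-form and degenerate cases", {
  bl <- blob_data(seed = 5L, sep = 9)
  one <- kmeans_fit(bl$x, 1L, seed = 2L)
  expect_equal(as.numeric(one$centers), colMeans(bl$x))
  expect_equal(one$inertia, sum(sweep(bl$x, 2, colMeans(bl$x))^2))
  three <- kmeans_fit(bl$x, 3L, seed = 2L)
  expect_equal(adjusted_rand_index(three$cluster, bl$labels), 1)
  x_small <- bl$x[1:6, ]
  all_k <- kmeans_fit(x_small, 6L, seed = 2L)
  expect_equal(all_k$inertia, 0)
  expect_error(kmeans_fit(x_small, 7L, seed = 1L), "exceeds")
  expect_identical(kmeans_fit(bl$x, 3L, seed = 9L),
                   kmeans_fit(bl$x, 3L, seed = 9L))
})

test_that("consensus matrix is a valid co-clustering frequency matrix", {
  bl <- blob_data(n_per = 30L, sep = 10, seed = 6L)
  cc <- consensus_cluster(bl$x, 3L, runs = 20L, seed = 7L)
  C <- cc$consensus
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(diag(C), rep(1, nrow(C)))
  expect_identical(C, t(C))
  # perfectly separable data: exact 0/1 block structure
  expect_true(all(C %in% c(0, 1)))
  expect_equal(adjusted_rand_index(cc$assignment, bl$labels), 1)
  # single run: entries 0/1 and assignment matches that run
  cc1 <- consensus_cluster(bl$x, 3L, runs = 1L, seed = 8L)
  expect_true(all(cc1$consensus %in% c(0, 1)))
  expect_equal(adjusted_rand_index(cc1$assignment, cc1$runs_labels[, 1]), 1)
  expect_error(consensus_cluster(bl$x, 3L, runs = 5L, seed = 1L, max_n = 10L),
               "max_n")
})

test_that("row permutation equivariance of consensus clustering", {
  bl <- blob_data(n_per = 20L, sep = 8, seed = 9L)
  perm <- with_seed(10L, sample(nrow(bl$x)))
  cc <- consensus_cluster(bl$x, 3L, runs = 10L, seed = 11L)
  cc_p <- consensus_cluster(bl$x[perm, ], 3L, runs = 10L, seed = 11L)
  expect_equal(adjusted_rand_index(cc_p$assignment, cc$assignment[perm]), 1)
})

test_that("ARI matches the exhaustive pair-counting oracle", {
  # exhaustive: all 3^5 labelings of 5 points against two fixed references
  refs <- list(c(1L, 1L, 2L, 2L, 3L), c(1L, 2L, 1L, 2L, 1L))
  grid <- as.matrix(expand.grid(rep(list(1:3), 5)))
  for (ref in refs) {
    for (r in seq_len(nrow(grid))) {
      lab <- grid[r, ]
      expect_equal(adjusted_rand_index(lab, ref), ari_oracle(lab, ref),
                   tolerance = 1e-12)
    }
  }
  # random labeling pairs at n = 8
  with_seed(19L, for (i in 1:50) {
    a <- sample(1:4, 8, TRUE)
    b <- sample(1:3, 8, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                 tolerance = 1e-12)
  })
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI has the label-invariance and chance-level properties", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(7, 7, 5, 5, 9, 9)), 1)
  mean_ari <- with_seed(23L, mean(replicate(300, {
    adjusted_rand_index(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  })))
  expect_lt(abs(mean_ari), 0.02)
  # cross-check against an independent implementation
  skip_if_not_installed("mclust")
  with_seed(29L, for (i in 1:20) {
    a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  })
})

test_that("pairwise stability reports the median pairwise ARI", {
  l1 <- c(1, 1, 2, 2, 3, 3)
  st_same <- pairwise_stability(list(l1, l1, l1))
  expect_equal(st_same$median, 1)
  # two identical + one random: brute-force the three pairwise values
  l3 <- c(1, 2, 3, 1, 2, 3)
  st <- pairwise_stability(list(l1, l1, l3))
  vals <- c(adjusted_rand_index(l1, l1), adjusted_rand_index(l1, l3),
            adjusted_rand_index(l1, l3))
  expect_equal(st$median, sort(vals)[2])
  expect_equal(sort(st$ari), sort(vals))
  # strongly separated latent structure is stable across runs
  bl <- blob_data(n_per = 25L, sep = 5, seed = 31L)
  cc <- consensus_cluster(bl$x, 3L, runs = 10L, seed = 32L)
  expect_gte(pairwise_stability(cc$runs_labels)$median, 0.9)
  expect_error(pairwise_stability(list(l1)), "2 runs")
})
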