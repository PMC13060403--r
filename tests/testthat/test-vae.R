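test_that("KL divergence matches the closed form and is non-negative", {
  expect_equal(kld_term(matrix(0, 3, 4), matrix(0, 3, 4)), 0)
  expect_equal(kld_term(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  expect_equal(kld_term(matrix(1, 2, 2), matrix(0, 2, 2), n = 2), 1.0)
  # non-negativity over random encoder outputs
  with_seed(1L, for (i in 1:20) {
    mu <- matrix(rnorm(12), 3, 4)
    lv <- matrix(rnorm(12), 3, 4)
    expect_gte(kld_term(mu, lv), 0)
  })
  expect_error(kld_term(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(kld_term(matrix(0, 2, 2), matrix(0, 2, 2), n = 0), "positive")
})

test_that("warm-up and batch-dilation schedules match their closed forms", {
  sch <- training_schedule()
  expect_equal(beta_at_epoch(10, sch), 0)
  expect_equal(beta_at_epoch(79, sch), 0)
  expect_equal(beta_at_epoch(115, sch), 0.0005)
  expect_equal(beta_at_epoch(150, sch), 0.001)
  expect_equal(beta_at_epoch(299, sch), 0.001)
  expect_equal(batch_size_at_epoch(49, sch), 64L)
  expect_equal(batch_size_at_epoch(50, sch), 96L)
  expect_equal(batch_size_at_epoch(100, sch), 144L)
  expect_equal(batch_size_at_epoch(150, sch), 216L)
  sch32 <- training_schedule(base_batch_size = 32L)
  expect_equal(batch_size_at_epoch(100, sch32), 72L)
  expect_error(beta_at_epoch(300, sch), "epoch")
  expect_error(batch_size_at_epoch(-1, sch), "epoch")
})

test_that("reconstruction losses are masked and normalized as defined", {
  fx <- trained_fixture()
  pm <- fx$pm
  x <- pm$x[1:6, , drop = FALSE]
  m <- pm$mask[1:6, , drop = FALSE]
  # perfect reconstruction: both terms zero on observed entries
  perfect <- reconstruction_losses(x, x, m, pm$column_map)
  expect_equal(perfect$Econ, 0)
  expect_equal(perfect$Ecat, 0)
  # single observed continuous entry off by 1 contributes 1 / (n_con * N)
  cont_cols <- which(pm$column_map$type == "continuous")
  n_con <- length(cont_cols)
  recon <- x
  j <- cont_cols[1]
  i <- which(!m[, j])[1]
  recon[i, j] <- x[i, j] - 1
  one <- reconstruction_losses(x, recon, m, pm$column_map)
  expect_equal(one$Econ, 1 / (n_con * 6))
  # fully-masked categorical feature contributes nothing
  cat_feat <- unique(pm$column_map$feature[pm$column_map$type == "categorical"])[1]
  cols <- which(pm$column_map$feature == cat_feat)
  m2 <- m; m2[, cols] <- TRUE
  x2 <- x; x2[, cols] <- 0
  recon_bad <- x2
  recon_bad[, cols[1]] <- 1  # garbage prediction where everything is missing
  masked <- reconstruction_losses(x2, recon_bad, m2, pm$column_map)
  ref <- reconstruction_losses(x2, x2, m2, pm$column_map)
  expect_equal(masked$Ecat, ref$Ecat)
  expect_error(
    reconstruction_losses(x, {r <- x; r[, cols[1]] <- 2; r}, m, pm$column_map),
    "probabilities")
})

test_that("masked entries influence neither loss, gradients nor latent means", {
  fx <- trained_fixture()
  pm <- fx$pm
  model <- fx$model
  rows <- which(rowSums(pm$mask) > 0)[1:8]
  x <- pm$x[rows, , drop = FALSE]
  m <- pm$mask[rows, , drop = FALSE]
  base <- vae_batch_loss(model, x, m, beta = 0.001, return_grads = TRUE)
  x_pert <- x
  x_pert[m] <- 99  # scribble over every stored placeholder
  pert <- vae_batch_loss(model, x_pert, m, beta = 0.001, return_grads = TRUE)
  expect_identical(base$L, pert$L)
  expect_identical(base$mu, pert$mu)
  expect_identical(base$grads, pert$grads)
})

test_that("training reduces the loss, logs the schedules and is seed-deterministic", {
  fx <- trained_fixture()
  h <- fx$model$history
  expect_lt(h$L[nrow(h)], h$L[1])
  expect_true(all(is.finite(h$L)))
  # loss identity at every logged epoch
  expect_equal(h$L, h$Ecat + h$Econ + h$beta * h$KLD, tolerance = 1e-12)
  # logged schedules match the closed-form operations
  expect_equal(h$beta, vapply(h$epoch, beta_at_epoch, numeric(1),
                              schedule = fx$sch,
                              beta_final = fx$cfg$beta_final))
  expect_equal(h$batch_size, vapply(h$epoch, batch_size_at_epoch, integer(1),
                                    schedule = fx$sch))
  # determinism: same seed, same final encoder means
  model2 <- train_vae(fx$pm, fx$cfg, fx$sch)
  expect_identical(encode(fx$model, fx$pm), encode(model2, fx$pm))
})

test_that("encoding is a deterministic function of the observed input", {
  fx <- trained_fixture()
  pm <- fx$pm
  mu <- encode(fx$model, pm)
  expect_true(all(is.finite(mu)))
  expect_equal(nrow(mu), nrow(pm$x))
  # duplicate rows encode identically
  pm_dup <- pm
  pm_dup$x[2, ] <- pm$x[1, ]
  pm_dup$mask[2, ] <- pm$mask[1, ]
  mu_dup <- encode(fx$model, pm_dup)
  expect_identical(mu_dup[1, ], mu_dup[2, ])
  # an all-missing row encodes without error
  pm_all <- pm
  pm_all$mask[3, ] <- TRUE
  expect_true(all(is.finite(encode(fx$model, pm_all)[3, ])))
  # column-map mismatch is rejected
  pm_bad <- pm
  pm_bad$column_map$feature[1] <- "other"
  expect_error(encode(fx$model, pm_bad), "column map")
})

test_that("evaluation metrics hit their analytic anchors", {
  fx <- trained_fixture()
  pm <- fx$pm
  ev <- evaluate_vae(fx$model, pm)
  expect_true(ev$cosine_recon >= -1 && ev$cosine_recon <= 1)
  expect_true(ev$topprob_match >= 0 && ev$topprob_match <= 1)
  # identity-reconstruction anchor via the loss path: a model is not needed,
  # the metric definitions are exercised directly on crafted reconstructions
  lay_cont <- which(pm$column_map$type == "continuous")
  x <- pm$x[1:5, , drop = FALSE]
  m <- pm$mask[1:5, , drop = FALSE]
  ident <- reconstruction_losses(x, x, m, pm$column_map)
  expect_equal(ident$Econ + ident$Ecat, 0)
})

test_that("beta = 0 gives a masked autoencoder whose history still logs KLD", {
  fx <- trained_fixture()
  cfg0 <- vae_config(hidden_layers = 8L, latent_dim = 3L, beta_final = 0,
                     learning_rate = 5e-3)
  sch <- training_schedule(total_epochs = 5L, warmup_start = 1L,
                           warmup_end = 2L, dilation_epochs = integer(0),
                           base_batch_size = 32L, seed = 3L)
  model <- train_vae(fx$pm, cfg0, sch, rows = 1:100)
  h <- model$history
  expect_true(all(h$beta == 0))
  expect_true(all(h$KLD >= 0))
  expect_equal(h$L, h$Ecat + h$Econ)
})

test_that("feature importance ranks the separating feature first and zeroes the null", {
  # cohort where one continuous feature carries all cluster separation
  spec <- cohort_spec(n_individuals = 300L, k_true = 2L, separation = 0,
                      n_binary = 0L, n_count = 0L, n_continuous = 5L,
                      n_categorical = 0L, missing_rate = 0, seed = 61L)
  g <- generate_cohort(spec)
  g$table$con_1 <- g$table$con_1 + ifelse(g$truth$cluster == 1L, 4, -4)
  pm <- fit_transform(g$table, g$metadata)
  cfg <- vae_config(hidden_layers = 16L, latent_dim = 2L,
                    learning_rate = 5e-3, beta_final = 0.01)
  sch <- training_schedule(total_epochs = 12L, warmup_start = 4L,
                           warmup_end = 8L, dilation_epochs = integer(0),
                           base_batch_size = 32L, seed = 7L)
  model <- train_vae(pm, cfg, sch)
  imp <- feature_importance(model, pm)
  expect_equal(imp$feature[1], "con_1")
  # encoder that ignores a feature scores exactly zero for it
  j <- which(pm$column_map$feature == "con_2")
  model0 <- model
  model0$enc_lin[[1]]$W[j, ] <- 0
  imp0 <- feature_importance(model0, pm, features = "con_2")
  expect_equal(imp0$impact, 0)
  expect_error(feature_importance(model, pm, features = "nope"), "unknown")
})

test_that("grid search ranks coherently and records failures", {
  fx <- trained_fixture()
  pm <- fx$pm
  pm$split <- rep(c("train", "test"), length.out = nrow(pm$x))
  sch <- training_schedule(total_epochs = 4L, warmup_start = 1L,
                           warmup_end = 2L, dilation_epochs = integer(0),
                           base_batch_size = 32L, seed = 9L)
  grid <- list(
    list(hidden_layers = 8L, latent_dim = 3L, learning_rate = 5e-3),
    list(hidden_layers = 12L, latent_dim = 4L, learning_rate = 5e-3))
  res <- grid_search(pm, grid, sch)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$rank, 1:2)
  expect_false(any(res$failed))
  # degenerate one-element grid ranks first
  res1 <- grid_search(pm, grid[1], sch)
  expect_equal(res1$rank, 1L)
  expect_error(grid_search(pm, list(), sch), "empty")
})

test_that("stability comparison is rotation-invariant and detects noise", {
  with_seed(13L, {
    emb <- matrix(rnorm(200 * 4), 200, 4)
    q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    pairs <- cbind(sample(200, 500, TRUE), sample(200, 500, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    same <- latentstrat:::embedding_similarity_difference(emb, emb, pairs)
    rotated <- latentstrat:::embedding_similarity_difference(emb, emb %*% q, pairs)
    random <- latentstrat:::embedding_similarity_difference(
      emb, matrix(rnorm(200 * 4), 200, 4), pairs)
    expect_equal(same, 0)
    expect_lt(rotated, 1e-10)
    expect_gt(random, 0.1)
  })
})
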