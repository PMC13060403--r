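#' Evaluate reconstruction quality and test log-likelihood
#'
#' Reconstruction error is summarized as the mean cosine similarity between
#' each sample's observed continuous sub-vector and its reconstruction, plus
#' the fraction of observed categorical entries whose argmax reconstruction
#' matches the truth; missing data are excluded throughout. The test
#' log-likelihood is the negative total loss (negative evidence bound) on
#' the evaluated rows.
#'
#' @param model a trained `vae_model`.
#' @param pm a `preprocessed_matrix`.
#' @param rows row subset to evaluate (e.g. `which(pm$split == "test")`);
#'   default all rows.
#' @return list: `cosine_recon`, `topprob_match`, `test_loglik`,
#'   `n_skipped_cosine` (samples without observed continuous entries).
#' @export
evaluate_vae <- function(model, pm, rows = NULL) {
  rows <- rows %||% seq_len(nrow(pm$x))
  X <- pm$x[rows, , drop = FALSE]
  M <- pm$mask[rows, , drop = FALSE]
  fw <- vae_forward(model, X, M, training = FALSE, eps = 0)
  lay <- model$layout
  cos_vals <- rep(NA_real_, nrow(X))
  if (lay$n_con > 0) {
    xc <- X[, lay$cont, drop = FALSE]
    rc <- fw$recon[, lay$cont, drop = FALSE]
    obs <- !M[, lay$cont, drop = FALSE]
    for (i in seq_len(nrow(X))) {
      o <- obs[i, ]
      if (!any(o)) next
      a <- xc[i, o]; b <- rc[i, o]
      na <- sqrt(sum(a^2)); nb2 <- sqrt(sum(b^2))
      cos_vals[i] <- if (na < 1e-12 || nb2 < 1e-12) 0 else sum(a * b) / (na * nb2)
    }
  }
  match_n <- 0L; match_hit <- 0L
  for (g in lay$groups) {
    obs <- !M[, g[1]]
    if (!any(obs)) next
    truth <- max.col(X[obs, g, drop = FALSE], ties.method = "first")
    pred <- max.col(fw$recon[obs, g, drop = FALSE], ties.method = "first")
    match_n <- match_n + length(truth)
    match_hit <- match_hit + sum(truth == pred)
  }
  losses <- reconstruction_losses(X, fw$recon, M, model$column_map)
  kld <- kld_term(fw$mu, fw$logvar)
  list(cosine_recon = mean(cos_vals, na.rm = TRUE),
       topprob_match = if (match_n > 0) match_hit / match_n else NA_real_,
       test_loglik = -(losses$Ecat + losses$Econ +
                         model$config$beta_final * kld),
       n_skipped_cosine = sum(is.na(cos_vals)))
}

n_parameters <- function(model) {
  cnt <- function(l) length(l$W) + length(l$b)
  sum(vapply(model$enc_lin, cnt, 0)) + sum(vapply(model$dec_lin, cnt, 0)) +
    cnt(model$mu_head) + cnt(model$lv_head) + cnt(model$out_head) +
    sum(vapply(model$enc_bn, function(l) 2 * length(l$gamma), 0)) +
    sum(vapply(model$dec_bn, function(l) 2 * length(l$gamma), 0))
}

#' Grid search over VAE hyperparameters
#'
#' Trains one model per configuration on the training split and evaluates
#' train/test reconstruction metrics and test log-likelihood. Configurations
#' are ranked by the unweighted mean of the per-metric ranks (train and test
#' cosine similarity, train and test top-probability match, test
#' log-likelihood; higher is better for all), ties broken toward the smaller
#' parameter count; the top 10 are flagged. A configuration that fails to
#' train is recorded as failed, never silently dropped.
#'
#' @param pm a `preprocessed_matrix` with a train/test split.
#' @param grid list of lists; each element may carry any [vae_config()]
#'   fields plus `base_batch_size`.
#' @param schedule base [training_schedule()] (epochs typically reduced for
#'   tuning).
#' @return data.frame with one row per configuration, metric columns,
#'   `aggregate_rank`, `rank`, `top10` and `failed`.
#' @export
grid_search <- function(pm, grid, schedule = training_schedule()) {
  if (!length(grid)) fail("empty hyperparameter grid")
  train_rows <- which(pm$split == "train")
  test_rows <- which(pm$split == "test")
  if (!length(test_rows)) fail("grid search needs a test split")
  rows <- lapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    cfg <- vae_config(
      hidden_layers = g$hidden_layers %||% 600L,
      latent_dim = g$latent_dim %||% 40L,
      dropout_rate = g$dropout_rate %||% 0.2,
      beta_final = g$beta_final %||% 0.001,
      learning_rate = g$learning_rate %||% 1e-4)
    sch <- schedule
    sch$base_batch_size <- as.integer(g$base_batch_size %||%
                                        schedule$base_batch_size)
    sch$seed <- derive_seed(schedule$seed, 100L + i)
    res <- tryCatch({
      model <- train_vae(pm, cfg, sch, rows = train_rows)
      ev_tr <- evaluate_vae(model, pm, train_rows)
      ev_te <- evaluate_vae(model, pm, test_rows)
      data.frame(config = i,
                 hidden = paste(cfg$hidden_layers, collapse = "x"),
                 latent_dim = cfg$latent_dim,
                 batch_size = sch$base_batch_size,
                 beta_final = cfg$beta_final,
                 n_params = n_parameters(model),
                 train_cosine = ev_tr$cosine_recon,
                 test_cosine = ev_te$cosine_recon,
                 train_match = ev_tr$topprob_match,
                 test_match = ev_te$topprob_match,
                 test_loglik = ev_te$test_loglik,
                 failed = FALSE)
    }, error = function(e) {
      data.frame(config = i,
                 hidden = paste(g$hidden_layers %||% 600L, collapse = "x"),
                 latent_dim = g$latent_dim %||% 40L,
                 batch_size = as.integer(g$base_batch_size %||%
                                           schedule$base_batch_size),
                 beta_final = g$beta_final %||% 0.001,
                 n_params = NA_integer_, train_cosine = NA_real_,
                 test_cosine = NA_real_, train_match = NA_real_,
                 test_match = NA_real_, test_loglik = NA_real_,
                 failed = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  metrics <- c("train_cosine", "test_cosine", "train_match", "test_match",
               "test_loglik")
  rk <- vapply(metrics, function(m) {
    v <- out[[m]]
    r <- rank(-v, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- nrow(out)  # failed configurations rank last
    r
  }, numeric(nrow(out)))
  rk <- matrix(rk, nrow = nrow(out))
  out$aggregate_rank <- rowMeans(rk)
  ord <- order(out$aggregate_rank, out$n_params, out$config)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out$top10 <- out$rank <= 10L
  out[order(out$rank), ]
}

## mean |cos_a - cos_b| over a fixed subsample of sample pairs
embedding_similarity_difference <- function(emb_a, emb_b, pairs) {
  cos_rows <- function(emb, i, j) {
    num <- rowSums(emb[i, , drop = FALSE] * emb[j, , drop = FALSE])
    den <- sqrt(rowSums(emb[i, , drop = FALSE]^2)) *
      sqrt(rowSums(emb[j, , drop = FALSE]^2))
    num / pmax(den, 1e-12)
  }
  mean(abs(cos_rows(emb_a, pairs[, 1], pairs[, 2]) -
             cos_rows(emb_b, pairs[, 1], pairs[, 2])))
}

#' Stability selection among candidate configurations
#'
#' Each candidate is retrained `n_retrain` times from different seeds; for
#' every pair of retrainings the latent embeddings are compared through the
#' mean absolute difference of sample-pair cosine similarities over a fixed
#' random subsample of pairs (a rotation-invariant comparison). The
#' configuration with the smallest average difference is the most stable.
#'
#' @param pm a `preprocessed_matrix`.
#' @param configs list of [vae_config()]-field lists (as in [grid_search()]).
#' @param schedule base [training_schedule()].
#' @param n_retrain retrainings per candidate (>= 2).
#' @param n_pairs sample pairs used in the comparison (default 10000, capped
#'   at the number of available pairs).
#' @return list: `best` (index of the winning configuration), `summary`
#'   data.frame with the mean pairwise difference per candidate.
#' @export
stability_select <- function(pm, configs, schedule = training_schedule(),
                             n_retrain = 10L, n_pairs = 10000L) {
  if (n_retrain < 2) fail("n_retrain must be >= 2")
  n <- nrow(pm$x)
  n_pairs <- min(n_pairs, n * (n - 1) / 2)
  pairs <- with_seed(derive_seed(schedule$seed, 77L), {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i, j)
  })
  summary <- lapply(seq_along(configs), function(ci) {
    g <- configs[[ci]]
    cfg <- vae_config(
      hidden_layers = g$hidden_layers %||% 600L,
      latent_dim = g$latent_dim %||% 40L,
      dropout_rate = g$dropout_rate %||% 0.2,
      beta_final = g$beta_final %||% 0.001,
      learning_rate = g$learning_rate %||% 1e-4)
    embs <- lapply(seq_len(n_retrain), function(r) {
      sch <- schedule
      sch$seed <- derive_seed(schedule$seed, 1000L + 37L * ci + r)
      encode(train_vae(pm, cfg, sch), pm)
    })
    diffs <- c()
    for (a in seq_len(n_retrain - 1L)) {
      for (b in seq(a + 1L, n_retrain)) {
        diffs <- c(diffs,
                   embedding_similarity_difference(embs[[a]], embs[[b]], pairs))
      }
    }
    data.frame(config = ci, mean_difference = mean(diffs))
  })
  summary <- do.call(rbind, summary)
  list(best = summary$config[which.min(summary$mean_difference)],
       summary = summary)
}

#' Perturbation-based feature importance on the latent space
#'
#' For each input feature, a perturbed dataset is encoded in which that
#' feature is set to its missing representation (zero for continuous, an
#' all-zero one-hot group for categorical) while all other inputs are
#' unchanged. The per-sample impact is the sum of absolute changes across
#' latent dimensions; impacts are aggregated across samples into one score
#' per feature. Entries already missing contribute zero by construction.
#'
#' @param model a trained `vae_model`.
#' @param pm a compatible `preprocessed_matrix`.
#' @param features features to score (default all).
#' @param aggregate `"mean"` (scale-free, default) or `"sum"`.
#' @return data.frame `feature` / `impact`, sorted descending.
#' @export
feature_importance <- function(model, pm, features = NULL,
                               aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  features <- features %||% unique(pm$column_map$feature)
  unknown <- setdiff(features, pm$column_map$feature)
  if (length(unknown)) {
    fail("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  mu0 <- encode(model, pm)
  scores <- vapply(features, function(f) {
    cols <- which(pm$column_map$feature == f)
    pm2 <- pm
    pm2$x[, cols] <- 0
    pm2$mask[, cols] <- TRUE
    mu1 <- encode(model, pm2)
    impact <- rowSums(abs(mu1 - mu0))
    if (aggregate == "mean") mean(impact) else sum(impact)
  }, numeric(1))
  out <- data.frame(feature = features, impact = unname(scores))
  out[order(-out$impact), ]
}
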