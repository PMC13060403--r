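# Shared fixtures: small synthetic specs and a cached trained model. All
# fixtures are generated in code at test time; nothing binary on disk.

tiny_spec <- function(seed = 3L, ...) {
  args <- utils::modifyList(list(
    n_individuals = 60L, k_true = 2L, separation = 1,
    n_binary = 3L, n_count = 3L, n_continuous = 4L, n_categorical = 2L,
    n_categories = 3L, missing_rate = 0.1, seed = seed), list(...))
  do.call(cohort_spec, args)
}

gene_fixture <- function(seed = 4L, n = 40L, mult = c(1, 1)) {
  genes <- c("SETD1A", "TRIO", "GRIN2A", "SP4", "XPO7")
  tiny_spec(
    seed = seed, n_individuals = n,
    pgs_traits = list(SCZ = c(0.3, -0.3), MDD = c(0, 0)),
    gene_panel = stats::setNames(c(0.1, 0.2, 0.3, 0.1, 0.4), genes),
    gene_sets = list(core = genes[1:2], extended = genes[1:4]),
    burden_multipliers = cbind(core = mult, extended = c(1, 1)))
}

# preprocessed matrix + trained model on a separable cohort, cached per
# session because several tests reuse it
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- tiny_spec(seed = 8L, n_individuals = 300L, k_true = 3L,
                      separation = 3, missing_rate = 0.05)
    g <- generate_cohort(spec)
    pm <- fit_transform(g$table, g$metadata)
    cfg <- vae_config(hidden_layers = 24L, latent_dim = 6L,
                      learning_rate = 5e-3)
    sch <- training_schedule(total_epochs = 15L, warmup_start = 5L,
                             warmup_end = 10L, dilation_epochs = 10L,
                             base_batch_size = 32L, seed = 5L)
    cache <<- list(spec = spec, cohort = g, pm = pm, cfg = cfg, sch = sch,
                   model = train_vae(pm, cfg, sch))
    cache
  }
})

# three well-separated Gaussian blobs for clustering tests
blob_data <- function(n_per = 60L, sep = 5, p = 3L, seed = 11L) {
  set.seed(seed)
  centers <- rbind(rep(0, p), c(sep, rep(0, p - 1)),
                   c(0, sep, rep(0, p - 2)))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(stats::rnorm(n_per * p), n_per, p), 2, centers[i, ], "+")
  }))
  list(x = x, labels = rep(1:3, each = n_per))
}

# brute-force pair-counting adjusted Rand index (independent oracle)
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}
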