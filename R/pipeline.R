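#' Configure the two-stage stratification pipeline
#'
#' Stage 1 embeds and clusters the full case-control cohort (diagnostic
#' separation, typically k = 2); stage 2 retrains the model on the case
#' subset and re-stratifies it into finer subgroups. All stage seeds derive
#' from the master seed; every output file records the configuration hash
#' and seed.
#'
#' @param spec a [cohort_spec()] describing the synthetic cohort, or `NULL`
#'   when `table`/`metadata` are supplied directly to [run_two_stage()].
#' @param out_dir output directory for artifact TSVs.
#' @param seed master seed.
#' @param vae list of [vae_config()] fields applied at both stages.
#' @param epochs training epochs per stage.
#' @param base_batch_size mini-batch size.
#' @param k_stage1 clusters at stage 1 (default 2).
#' @param k_stage2 clusters at stage 2, or `"auto"` to take the validity
#'   panel's majority vote over `k_range`.
#' @param k_range candidate k for the stage-2 validity vote.
#' @param consensus_runs k-means runs per consensus matrix.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, out_dir = tempfile("latentstrat_"),
                            seed = 1L, vae = list(), epochs = 30L,
                            base_batch_size = 64L, k_stage1 = 2L,
                            k_stage2 = "auto", k_range = 2:6,
                            consensus_runs = 25L) {
  structure(list(spec = spec, out_dir = out_dir, seed = as.integer(seed),
                 vae = vae, epochs = as.integer(epochs),
                 base_batch_size = as.integer(base_batch_size),
                 k_stage1 = as.integer(k_stage1), k_stage2 = k_stage2,
                 k_range = k_range, consensus_runs = as.integer(consensus_runs)),
            class = "pipeline_config")
}

stage_schedule <- function(config, stage_offset) {
  epochs <- config$epochs
  training_schedule(
    total_epochs = epochs,
    warmup_start = max(1L, min(80L, floor(epochs / 3))),
    warmup_end = max(2L, min(150L, floor(2 * epochs / 3))),
    dilation_epochs = c(50L, 100L, 150L)[c(50L, 100L, 150L) < epochs],
    base_batch_size = config$base_batch_size,
    seed = derive_seed(config$seed, stage_offset))
}

stage_vae_config <- function(config) {
  v <- config$vae
  vae_config(hidden_layers = v$hidden_layers %||% 64L,
             latent_dim = v$latent_dim %||% 10L,
             dropout_rate = v$dropout_rate %||% 0.2,
             beta_final = v$beta_final %||% 0.001,
             learning_rate = v$learning_rate %||% 5e-3)
}

run_stage <- function(table, metadata, config, k, stage_name, stage_offset) {
  pm <- fit_transform(table, metadata)
  model <- train_vae(pm, stage_vae_config(config),
                     stage_schedule(config, stage_offset))
  mu <- encode(model, pm)
  hop <- hopkins_statistic(mu, seed = derive_seed(config$seed,
                                                  stage_offset + 1L))
  validity <- NULL
  if (identical(k, "auto")) {
    validity <- validity_panel(mu, config$k_range,
                               seed = derive_seed(config$seed,
                                                  stage_offset + 2L))
    k <- validity$majority_k
  }
  cc <- consensus_cluster(mu, k, runs = config$consensus_runs,
                          seed = derive_seed(config$seed, stage_offset + 3L))
  stability <- pairwise_stability(cc$runs_labels)
  importance <- feature_importance(model, pm)
  composition <- cluster_composition(cc$assignment, table$case_status)
  list(name = stage_name, pm = pm, model = model, latent = mu, k = k,
       hopkins = hop, validity = validity, consensus = cc,
       stability = stability, importance = importance,
       composition = composition,
       assignment = data.frame(id = table$id, cluster = cc$assignment,
                               stringsAsFactors = FALSE))
}

#' Run the two-stage stratification pipeline
#'
#' Stage 1: preprocess the full cohort, train the VAE, test clusterability,
#' consensus-cluster the latent space at `k_stage1` and profile the
#' composition and feature enrichment. Stage 2: retrain on the case subset,
#' choose k (validity vote or configured), re-cluster and run PGS and
#' rare-variant burden enrichment when those inputs exist. Intermediates are
#' written as TSVs stamped with the configuration hash and seed; a stage
#' failure halts with the stage name while prior artifacts persist.
#'
#' @param config a [pipeline_config()].
#' @param table,metadata optional cohort table + metadata (default:
#'   generated from `config$spec`).
#' @param pgs optional PGS table (default from the spec's `pgs_traits`).
#' @param burden optional burden matrix (default from the spec's
#'   `gene_panel`).
#' @return artifact bundle (list) with `stage1`, `stage2`, `files`,
#'   `config_hash`.
#' @export
run_two_stage <- function(config, table = NULL, metadata = NULL, pgs = NULL,
                          burden = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  stamp <- c(sprintf("config_hash=%s", chash),
             sprintf("seed=%d", config$seed))
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(x, path, comment = stamp)
    files[[name]] <<- path
    path
  }
  truth <- NULL
  if (is.null(table)) {
    if (is.null(config$spec)) fail("stage 'simulate' failed: no spec and no table")
    gen <- generate_cohort(config$spec)
    table <- gen$table
    metadata <- gen$metadata
    truth <- gen$truth
    if (length(config$spec$pgs_traits) && is.null(pgs)) {
      pgs <- generate_pgs(config$spec, truth)
    }
    if (length(config$spec$gene_panel) && is.null(burden)) {
      burden <- generate_variant_data(config$spec, truth, format = "matrix")
    }
  }
  run_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      fail("stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  s1 <- run_guard("stage1", run_stage(table, metadata, config,
                                      config$k_stage1, "stage1", 1000L))
  emit(s1$assignment, "stage1_assignment.tsv")
  emit(s1$composition, "stage1_composition.tsv")
  emit(s1$importance, "stage1_feature_importance.tsv")
  emit(s1$model$history, "stage1_training_history.tsv")

  cases <- which(table$case_status == "case")
  s2 <- run_guard("stage2", run_stage(table[cases, , drop = FALSE], metadata,
                                      config, config$k_stage2, "stage2",
                                      2000L))
  emit(s2$assignment, "stage2_assignment.tsv")
  emit(s2$importance, "stage2_feature_importance.tsv")
  if (!is.null(s2$validity)) emit(s2$validity$votes, "stage2_validity_votes.tsv")

  covars <- table[cases, covariate_names(), drop = FALSE]
  enrich <- list()
  if (!is.null(pgs)) {
    pgs_cases <- pgs[match(table$id[cases], pgs$id), , drop = FALSE]
    std <- normalize_pgs(pgs, table$case_status == "control")
    std_cases <- std[match(table$id[cases], std$id), , drop = FALSE]
    traits <- setdiff(names(std_cases), "id")
    enrich$pgs <- run_guard("enrich_pgs", enrichment_scan(
      std_cases[, traits, drop = FALSE],
      rep("continuous", length(traits)),
      s2$assignment$cluster, covariates = covars, family_label = "pgs"))
    emit(enrich$pgs, "stage2_pgs_enrichment.tsv")
  }
  if (!is.null(burden)) {
    sets <- lapply(names(config$spec$gene_sets %||% list()), function(nm) {
      gene_set(nm, config$spec$gene_sets[[nm]])
    })
    if (!length(sets)) sets <- list(gene_set("all_genes", colnames(burden)))
    agg <- aggregate_genesets(burden, sets)
    agg_cases <- agg[match(table$id[cases], agg$id), , drop = FALSE]
    set_names <- setdiff(names(agg_cases), "id")
    enrich$burden <- run_guard("enrich_burden", enrichment_scan(
      agg_cases[, set_names, drop = FALSE],
      rep("count", length(set_names)),
      s2$assignment$cluster, covariates = covars,
      family_label = "rare_variant"))
    emit(enrich$burden, "stage2_burden_enrichment.tsv")
  }
  bundle <- list(stage1 = s1, stage2 = s2, enrichment = enrich,
                 truth = truth, files = files, config = config,
                 config_hash = chash)
  class(bundle) <- "latentstrat_bundle"
  bundle
}

#' Render a human-readable pipeline report
#'
#' Markdown summary of an artifact bundle: cluster composition, Hopkins
#' clusterability, validity votes and significance, stability, top features
#' by importance, and enrichment tables with significance stars.
#' Regeneration is idempotent: the same bundle always renders the same text.
#'
#' @param bundle output of [run_two_stage()].
#' @param path optional file to write; default returns the text invisibly.
#' @return character vector of report lines (invisibly when written).
#' @export
report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "latentstrat_bundle"))
  fmt_tab <- function(df, digits = 3) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  sec <- function(title, lines) c(paste0("## ", title), "", lines, "")
  l <- c(sprintf("# Stratification report (config %s, seed %d)",
                 bundle$config_hash, bundle$config$seed), "")
  for (st in list(bundle$stage1, bundle$stage2)) {
    l <- c(l, sec(
      sprintf("%s (k = %d)", st$name, st$k),
      c(sprintf("Hopkins statistic: %.4f (complement %.4f; low = clustered)",
                st$hopkins$H, st$hopkins$complement),
        sprintf("Median pairwise ARI across %d consensus runs: %.3f",
                st$consensus$runs, st$stability$median),
        "", "### Composition", fmt_tab(st$composition),
        "", "### Top features by latent impact",
        fmt_tab(utils::head(st$importance, 10)))))
    if (!is.null(st$validity)) {
      l <- c(l, sec("Validity votes", fmt_tab(st$validity$votes)))
    }
  }
  if (length(bundle$enrichment)) {
    for (nm in names(bundle$enrichment)) {
      e <- bundle$enrichment[[nm]]
      kept <- e[!e$excluded, , drop = FALSE]
      l <- c(l, sec(
        paste0("Enrichment: ", nm),
        if (nrow(kept)) {
          fmt_tab(kept[, c("outcome", "cluster", "family", "effect_type",
                           "effect", "p", "p_bonf", "q_fdr", "stars_bonf",
                           "stars_fdr")])
        } else {
          "No tests passed the event filters."
        }))
    }
  } else {
    l <- c(l, sec("Enrichment", "No tests passed filters."))
  }
  l <- unname(l)
  if (!is.null(path)) {
    writeLines(l, path)
    return(invisible(l))
  }
  l
}
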