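#' Specify a synthetic registry-style cohort
#'
#' Defines the generative model for a synthetic case-control cohort with
#' planted latent cluster structure, emulating the statistical shape of
#' registry-derived clinical data: mixed binary / categorical / count /
#' continuous feature blocks, missing-at-random entries, overdispersed counts,
#' cluster-shifted polygenic scores and cluster-rate-modulated per-gene
#' rare-allele counts. It replaces access-restricted registry and exome data
#' for development and testing; it does not emulate longitudinal trajectories
#' or ICD code hierarchies.
#'
#' @param n_individuals number of individuals (rows).
#' @param case_fraction baseline case probability in (0,1).
#' @param k_true number of planted latent clusters (>= 1).
#' @param separation non-negative scalar scaling between-cluster mean shifts,
#'   in within-cluster SD units. 0 plants no structure.
#' @param n_binary,n_count,n_continuous,n_categorical feature-block sizes
#'   (each >= 0; their sum must be >= 1).
#' @param n_categories categories per categorical feature (>= 2).
#' @param missing_rate per-entry missing-at-random probability in [0,1),
#'   applied independently to feature entries (never labels or covariates).
#' @param count_dispersion negative-binomial size parameter for count
#'   features; `Inf` gives Poisson counts.
#' @param mixing optional per-cluster mixing proportions (length `k_true`,
#'   summing to 1); default equal.
#' @param case_rate_by_cluster optional per-cluster case probability (length
#'   `k_true`); default `case_fraction` in every cluster. Use unequal rates to
#'   plant a case/control axis aligned with the latent structure.
#' @param pgs_traits named list: trait name -> numeric vector of per-cluster
#'   mean shifts (in SD units, length `k_true`).
#' @param gene_panel named numeric vector: gene symbol -> baseline per-gene
#'   rare-allele rate (> 0).
#' @param gene_sets named list of character vectors of gene symbols; used to
#'   target `burden_multipliers`.
#' @param burden_multipliers optional matrix (`k_true` rows, one column per
#'   gene set, dimnames required) of strictly positive per-cluster rate
#'   multipliers; default all 1 (no genetic cluster signal).
#' @param seed integer seed; the spec is deterministic given the seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals,
                        case_fraction = 0.5,
                        k_true = 3L,
                        separation = 2,
                        n_binary = 20L,
                        n_count = 20L,
                        n_continuous = 20L,
                        n_categorical = 5L,
                        n_categories = 3L,
                        missing_rate = 0.1,
                        count_dispersion = Inf,
                        mixing = NULL,
                        case_rate_by_cluster = NULL,
                        pgs_traits = list(),
                        gene_panel = numeric(0),
                        gene_sets = list(),
                        burden_multipliers = NULL,
                        seed = 1L) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1 || n_individuals != round(n_individuals)) {
    fail("field 'n_individuals' must be a positive integer")
  }
  check_prop(case_fraction, "case_fraction", lo_open = TRUE, hi_open = TRUE)
  if (k_true < 1 || k_true != round(k_true)) {
    fail("field 'k_true' must be an integer >= 1")
  }
  if (k_true > n_individuals) fail("field 'k_true' exceeds n_individuals")
  if (!is.numeric(separation) || separation < 0) {
    fail("field 'separation' must be non-negative")
  }
  blocks <- c(n_binary = n_binary, n_count = n_count,
              n_continuous = n_continuous, n_categorical = n_categorical)
  if (any(blocks < 0)) {
    fail("field '", names(blocks)[which(blocks < 0)[1]], "' must be >= 0")
  }
  if (sum(blocks) < 1) fail("feature block sizes must sum to >= 1")
  if (n_categorical > 0 && n_categories < 2) {
    fail("field 'n_categories' must be >= 2")
  }
  check_prop(missing_rate, "missing_rate", hi_open = TRUE)
  if (!(is.infinite(count_dispersion) || count_dispersion > 0)) {
    fail("field 'count_dispersion' must be positive or Inf")
  }
  mixing <- mixing %||% rep(1 / k_true, k_true)
  if (length(mixing) != k_true || any(mixing <= 0) ||
      abs(sum(mixing) - 1) > 1e-8) {
    fail("field 'mixing' must have length k_true, positive entries, sum 1")
  }
  case_rate_by_cluster <- case_rate_by_cluster %||% rep(case_fraction, k_true)
  if (length(case_rate_by_cluster) != k_true ||
      any(case_rate_by_cluster <= 0) || any(case_rate_by_cluster >= 1)) {
    fail("field 'case_rate_by_cluster' must be length k_true, in (0,1)")
  }
  for (tr in names(pgs_traits)) {
    if (length(pgs_traits[[tr]]) != k_true) {
      fail("pgs_traits['", tr, "'] must give one shift per cluster")
    }
  }
  if (length(gene_panel) && (is.null(names(gene_panel)) ||
                             any(gene_panel <= 0))) {
    fail("field 'gene_panel' must be a named vector of strictly positive rates")
  }
  if (!is.null(burden_multipliers)) {
    if (is.null(colnames(burden_multipliers)) ||
        nrow(burden_multipliers) != k_true ||
        any(burden_multipliers <= 0)) {
      fail("field 'burden_multipliers' must be a k_true x set matrix with ",
           "set column names and strictly positive entries")
    }
    missing_sets <- setdiff(colnames(burden_multipliers), names(gene_sets))
    if (length(missing_sets)) {
      fail("burden_multipliers references unknown gene set(s): ",
           paste(missing_sets, collapse = ", "))
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals), case_fraction = case_fraction,
    k_true = as.integer(k_true), separation = separation,
    n_binary = as.integer(n_binary), n_count = as.integer(n_count),
    n_continuous = as.integer(n_continuous),
    n_categorical = as.integer(n_categorical),
    n_categories = as.integer(n_categories),
    missing_rate = missing_rate, count_dispersion = count_dispersion,
    mixing = mixing, case_rate_by_cluster = case_rate_by_cluster,
    pgs_traits = pgs_traits, gene_panel = gene_panel, gene_sets = gene_sets,
    burden_multipliers = burden_multipliers, seed = as.integer(seed)
  ), class = "cohort_spec")
}

## Planted per-cluster parameters for every feature block. Directions are
## standardized across clusters (mean 0, SD 1 when k > 1) so `separation`
## is interpretable as a between-cluster shift in within-cluster SD units.
cluster_directions <- function(k, n) {
  z <- matrix(stats::rnorm(k * n), k, n)
  if (k > 1) {
    z <- sweep(z, 2, colMeans(z))
    s <- apply(z, 2, stats::sd)
    s[s < 1e-12] <- 1
    z <- sweep(z, 2, s, "/")
  } else {
    z[] <- 0
  }
  z
}

#' Generate a synthetic cohort table with ground truth
#'
#' Draws individuals from the planted mixture defined by a [cohort_spec()]:
#' binary features from cluster-specific Bernoulli rates, counts from
#' negative-binomial (Poisson when `count_dispersion = Inf`) with
#' cluster-specific means, continuous features from unit-variance Gaussians
#' with cluster mean shifts of magnitude `separation`, and categoricals from
#' cluster-tilted multinomials. Covariates (sex, age, cohort-wave indicator,
#' 10 genetic PCs) are generated independently of cluster membership. Entries
#' are then masked missing-at-random at `missing_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{table}{data.frame: `id`, `case_status`, covariates
#'       (`sex`, `age`, `wave`, `PC1`..`PC10`), then feature columns with
#'       `NA` marking missing entries.}
#'     \item{metadata}{data.frame `feature` / `type` / `n_categories`
#'       describing every feature column.}
#'     \item{truth}{ground truth: integer `cluster` per individual,
#'       `case_status`, and the planted per-cluster parameter tables in
#'       `effects`.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    n <- spec$n_individuals
    k <- spec$k_true
    cl <- sample.int(k, n, replace = TRUE, prob = spec$mixing)
    if (n >= k) {
      # guarantee non-empty clusters (GroundTruth invariant)
      cl[seq_len(k)] <- seq_len(k)
      cl <- cl[sample.int(n)]
    }
    case <- stats::rbinom(n, 1L, spec$case_rate_by_cluster[cl])
    covars <- data.frame(
      sex = stats::rbinom(n, 1L, 0.5),
      age = stats::runif(n, 18, 45),
      wave = stats::rbinom(n, 1L, 0.5)
    )
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))

    feats <- list()
    meta <- list()
    effects <- list()
    sep <- spec$separation

    if (spec$n_binary > 0) {
      base <- stats::runif(spec$n_binary, 0.1, 0.5)
      dirs <- cluster_directions(k, spec$n_binary)
      rates <- stats::plogis(sweep(0.5 * sep * dirs, 2,
                                   stats::qlogis(base), "+"))
      m <- matrix(stats::rbinom(n * spec$n_binary, 1L,
                                rates[cl, , drop = FALSE]),
                  n, spec$n_binary)
      colnames(m) <- paste0("bin_", seq_len(spec$n_binary))
      feats$binary <- m
      meta$binary <- data.frame(feature = colnames(m), type = "binary",
                                n_categories = 2L)
      effects$binary_rate <- rates
    }
    if (spec$n_count > 0) {
      base_mu <- stats::runif(spec$n_count, 0.5, 3)
      dirs <- cluster_directions(k, spec$n_count)
      mu <- exp(sweep(0.3 * sep * dirs, 2, log(base_mu), "+"))
      mu_i <- mu[cl, , drop = FALSE]
      m <- if (is.infinite(spec$count_dispersion)) {
        matrix(stats::rpois(n * spec$n_count, mu_i), n, spec$n_count)
      } else {
        matrix(stats::rnbinom(n * spec$n_count, size = spec$count_dispersion,
                              mu = mu_i), n, spec$n_count)
      }
      colnames(m) <- paste0("cnt_", seq_len(spec$n_count))
      feats$count <- m
      meta$count <- data.frame(feature = colnames(m), type = "count",
                               n_categories = NA_integer_)
      effects$count_mean <- mu
    }
    if (spec$n_continuous > 0) {
      dirs <- cluster_directions(k, spec$n_continuous)
      shift <- sep * dirs
      m <- matrix(stats::rnorm(n * spec$n_continuous), n, spec$n_continuous) +
        shift[cl, , drop = FALSE]
      colnames(m) <- paste0("con_", seq_len(spec$n_continuous))
      feats$continuous <- m
      meta$continuous <- data.frame(feature = colnames(m), type = "continuous",
                                    n_categories = NA_integer_)
      effects$continuous_mean <- shift
    }
    if (spec$n_categorical > 0) {
      nc <- spec$n_categories
      m <- matrix(NA_integer_, n, spec$n_categorical)
      probs <- array(NA_real_, c(k, nc, spec$n_categorical))
      for (f in seq_len(spec$n_categorical)) {
        base <- log(stats::runif(nc, 0.5, 1.5))
        tilt <- matrix(stats::rnorm(k * nc), k, nc)
        if (k > 1) tilt <- sweep(tilt, 2, colMeans(tilt)) else tilt[] <- 0
        lp <- sweep(0.5 * sep * tilt, 2, base, "+")
        p <- exp(lp) / rowSums(exp(lp))
        probs[, , f] <- p
        u <- stats::runif(n)
        cum <- t(apply(p, 1, cumsum))
        m[, f] <- 1L + rowSums(u > cum[cl, , drop = FALSE])
      }
      colnames(m) <- paste0("cat_", seq_len(spec$n_categorical))
      feats$categorical <- m
      meta$categorical <- data.frame(feature = colnames(m),
                                     type = "categorical", n_categories = nc)
      effects$categorical_prob <- probs
    }

    fmat <- do.call(cbind, lapply(feats, function(m) {
      storage.mode(m) <- "double"
      m
    }))
    # missing-at-random mask over feature entries only
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(length(fmat)) < spec$missing_rate,
                     nrow(fmat), ncol(fmat))
      fmat[miss] <- NA_real_
    }

    table <- data.frame(
      id = sprintf("ind_%05d", seq_len(n)),
      case_status = ifelse(case == 1L, "case", "control"),
      covars, pcs, fmat,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    list(table = table,
         metadata = metadata,
         truth = list(cluster = cl,
                      case_status = table$case_status,
                      effects = effects))
  })
}

#' Names of covariate columns in a cohort table
#' @return character vector of the standard covariate column names.
#' @export
covariate_names <- function() c("sex", "age", "wave", paste0("PC", 1:10))

#' Generate per-individual polygenic scores with planted cluster shifts
#'
#' Trait `t` for individual `i` is drawn `Normal(shift[t, cluster(i)], 1)`,
#' emulating raw polygenic scores whose per-cluster means differ by the
#' planted shifts (in SD units).
#'
#' @param spec a [cohort_spec()] with non-empty `pgs_traits`.
#' @param truth the `truth` element returned by [generate_cohort()].
#' @return data.frame with `id` and one numeric column per trait.
#' @export
generate_pgs <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!length(spec$pgs_traits)) fail("spec has no pgs_traits")
  cl <- truth$cluster
  if (length(cl) != spec$n_individuals) fail("truth labels do not match spec")
  if (any(cl < 1 | cl > spec$k_true)) fail("unknown cluster in truth labels")
  with_seed(derive_seed(spec$seed, 2L), {
    out <- data.frame(id = sprintf("ind_%05d", seq_along(cl)),
                      stringsAsFactors = FALSE)
    for (tr in names(spec$pgs_traits)) {
      shift <- spec$pgs_traits[[tr]]
      out[[tr]] <- stats::rnorm(length(cl), mean = shift[cl], sd = 1)
    }
    out
  })
}

## Effective per-cluster per-gene rates: baseline times the multiplier of
## every configured gene set containing the gene.
burden_rates <- function(spec) {
  genes <- names(spec$gene_panel)
  rate <- matrix(rep(spec$gene_panel, each = spec$k_true),
                 spec$k_true, length(genes), dimnames = list(NULL, genes))
  if (!is.null(spec$burden_multipliers)) {
    for (s in colnames(spec$burden_multipliers)) {
      members <- intersect(spec$gene_sets[[s]], genes)
      rate[, members] <- rate[, members] * spec$burden_multipliers[, s]
    }
  }
  rate
}

#' Generate rare-variant data (count matrix or VCF)
#'
#' Per-individual per-gene alternate-allele counts are Poisson with rate
#' `baseline_rate[gene] * multiplier[cluster, set]` for every configured gene
#' set containing the gene. With `format = "vcf"` the counts are additionally
#' materialized as a VCF v4.2 file whose biallelic records carry INFO keys
#' `CADD`, `AF` and `GENE`, per-sample `GT` genotypes consistent with the
#' counts, and decoy records that fail the CADD > 15 and AF < 1% filters
#' (including exact-boundary decoys) so filter behaviour is exercised.
#'
#' @param spec a [cohort_spec()] with a non-empty `gene_panel`.
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param format `"matrix"` or `"vcf"`.
#' @param path output file path (required for `format = "vcf"`).
#' @return for `"matrix"`, an integer matrix (individuals x genes, dimnames
#'   set); for `"vcf"`, a list with `path` and the ground-truth `counts`
#'   matrix that an ingest with the default filters must reproduce.
#' @export
generate_variant_data <- function(spec, truth, format = c("matrix", "vcf"),
                                  path = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  format <- match.arg(format)
  if (!length(spec$gene_panel)) fail("spec has an empty gene_panel")
  cl <- truth$cluster
  genes <- names(spec$gene_panel)
  counts <- with_seed(derive_seed(spec$seed, 3L), {
    rate <- burden_rates(spec)
    m <- matrix(stats::rpois(length(cl) * length(genes),
                             rate[cl, , drop = FALSE]),
                length(cl), length(genes))
    dimnames(m) <- list(sprintf("ind_%05d", seq_along(cl)), genes)
    m
  })
  if (format == "matrix") return(counts)
  if (is.null(path)) fail("format='vcf' requires 'path'")
  write_variant_vcf(counts, path, seed = derive_seed(spec$seed, 4L))
  list(path = path, counts = counts)
}

#' Write an alternate-allele count matrix as a synthetic annotated VCF
#'
#' Each gene's counts are spread over as many biallelic records as needed
#' (a diploid genotype carries at most 2 alternate alleles), with passing
#' records annotated CADD > 15 and AF < 0.01. Four decoy records per cohort
#' are appended that must be excluded by strict filtering: CADD below
#' threshold, CADD exactly 15, AF above threshold, and AF exactly 0.01.
#'
#' @param counts integer matrix, individuals x genes, dimnames set.
#' @param path output VCF path.
#' @param seed seed for the annotation jitter.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(counts, path, seed = 1L) {
  genes <- colnames(counts)
  ids <- rownames(counts)
  stopifnot(!is.null(genes), !is.null(ids))
  with_seed(seed, {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=1>",
      "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
      "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", ids), collapse = "\t")
    )
    pos <- 1000L
    rec <- function(pos, gene, cadd, af, gt) {
      paste(c("1", pos, sprintf("var_%d", pos), "A", "G", ".", "PASS",
              sprintf("CADD=%.4g;AF=%.6g;GENE=%s", cadd, af, gene),
              "GT", gt), collapse = "\t")
    }
    for (g in genes) {
      cnt <- counts[, g]
      nvar <- max(1L, ceiling(max(cnt) / 2))
      for (v in seq_len(nvar)) {
        dose <- pmin(2L, pmax(0L, cnt - 2L * (v - 1L)))
        gt <- c("0/0", "0/1", "1/1")[dose + 1L]
        # sprinkle missing genotypes onto zero-dose samples: they must
        # contribute 0 either way
        zero <- which(dose == 0L)
        if (length(zero)) {
          nmiss <- min(length(zero), max(0L, stats::rpois(1, 0.5)))
          if (nmiss > 0) gt[sample(zero, nmiss)] <- "./."
        }
        lines <- c(lines, rec(pos, g,
                              cadd = 15 + stats::runif(1, 0.5, 20),
                              af = stats::runif(1, 1e-4, 9e-3),
                              gt = gt))
        pos <- pos + 1L
      }
    }
    # decoys: all carry non-zero genotypes and must be filtered out
    het_all <- paste(rep("0/1", length(ids)), collapse = "\t")
    lines <- c(lines,
               rec(pos,     genes[1], cadd = 10,    af = 5e-3, gt = het_all),
               rec(pos + 1L, genes[1], cadd = 15,    af = 5e-3, gt = het_all),
               rec(pos + 2L, genes[1], cadd = 30,    af = 0.05, gt = het_all),
               rec(pos + 3L, genes[1], cadd = 30,    af = 0.01, gt = het_all))
    writeLines(lines, path)
  })
  invisible(path)
}
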