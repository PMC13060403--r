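#' Standardize polygenic scores against the control population
#'
#' For each trait, the standardized score is
#' `(raw - mean(controls)) / sd(controls)` with the sample SD (n - 1
#' denominator), so the control subset has mean 0 and SD 1 after
#' standardization; the transformation is idempotent on already-standardized
#' scores.
#'
#' @param pgs data.frame with `id` and one numeric column per trait.
#' @param control_mask logical vector marking control individuals.
#' @return data.frame of the same shape with standardized scores.
#' @export
normalize_pgs <- function(pgs, control_mask) {
  if (length(control_mask) != nrow(pgs)) {
    fail("control_mask length does not match the score table")
  }
  traits <- setdiff(names(pgs), "id")
  out <- pgs
  for (tr in traits) {
    x <- pgs[[tr]]
    ctl <- x[control_mask & is.finite(x)]
    if (length(ctl) < 2) fail("trait '", tr, "': need >= 2 finite controls")
    s <- stats::sd(ctl)
    if (s < 1e-12) fail("trait '", tr, "': zero control-score variance")
    out[[tr]] <- (x - mean(ctl)) / s
  }
  out
}

#' Ingest rare-variant burden from an annotated VCF
#'
#' Retains biallelic records with `CADD > cadd_min` and `AF < af_max` (both
#' strict, read from the INFO field) and accumulates each individual's
#' alternate-allele dosage (0/1/2 from GT; missing genotypes contribute 0)
#' into the record's gene. Multiallelic records are rejected with their
#' position — normalize (split) them upstream.
#'
#' @param vcf_path path to a VCF v4.2 file with INFO keys `CADD` (Float),
#'   `AF` (Float) and `GENE` (String) and per-sample GT.
#' @param cadd_min CADD threshold (default 15; strict >).
#' @param af_max allele-frequency threshold (default 0.01; strict <).
#' @return integer matrix individuals x genes with attributes
#'   `cadd_min`, `af_max` and `n_records_used`.
#' @export
ingest_vcf_burden <- function(vcf_path, cadd_min = 15, af_max = 0.01) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    fail("multiallelic record(s) at position(s) ",
         paste(fix[multi, "POS"], collapse = ", "),
         "; split multiallelic sites before ingestion")
  }
  cadd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CADD")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  gene <- vcfR::extract.info(v, "GENE")
  if (anyNA(cadd) || anyNA(af) || anyNA(gene) || is.null(gene)) {
    fail("every record must carry INFO keys CADD, AF and GENE")
  }
  keep <- cadd > cadd_min & af < af_max
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  genes <- unique(gene[keep])
  counts <- matrix(0L, length(ids), length(genes),
                   dimnames = list(ids, genes))
  dose_of <- function(g) {
    # alternate-allele dosage from a diploid GT string; missing -> 0
    d <- integer(length(g))
    d[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[g %in% c("1/1", "1|1")] <- 2L
    d
  }
  for (r in which(keep)) {
    counts[, gene[r]] <- counts[, gene[r]] + dose_of(gt[r, ])
  }
  attr(counts, "cadd_min") <- cadd_min
  attr(counts, "af_max") <- af_max
  attr(counts, "n_records_used") <- sum(keep)
  counts
}

#' Read a gene set from a plain-text file
#'
#' One gene symbol per line; the set name is the file stem. Symbols are
#' case-normalized to upper case and deduplicated.
#'
#' @param path file path.
#' @return an object of class `gene_set`: list with `name` and `genes`.
#' @export
read_gene_set <- function(path) {
  genes <- toupper(trimws(readLines(path)))
  genes <- unique(genes[nzchar(genes)])
  if (!length(genes)) fail("gene-set file '", path, "' is empty")
  gene_set(tools::file_path_sans_ext(basename(path)), genes)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols (case-normalized,
#'   deduplicated; must be non-empty).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) fail("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Aggregate per-gene burden into gene-set burden
#'
#' `burden(i, S) = sum over genes g in S of counts(i, g)`. Genes absent from
#' the matrix contribute 0 and are reported in the `missing_genes`
#' attribute.
#'
#' @param burden individuals x genes count matrix (from
#'   [ingest_vcf_burden()] or [generate_variant_data()]).
#' @param sets list of [gene_set()] objects (or a single one).
#' @return data.frame `id` plus one burden column per set, with attribute
#'   `missing_genes` (named list).
#' @export
aggregate_genesets <- function(burden, sets) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  out <- data.frame(id = rownames(burden), stringsAsFactors = FALSE)
  missing_genes <- list()
  for (s in sets) {
    stopifnot(inherits(s, "gene_set"))
    present <- intersect(s$genes, toupper(colnames(burden)))
    missing_genes[[s$name]] <- setdiff(s$genes, toupper(colnames(burden)))
    cols <- which(toupper(colnames(burden)) %in% present)
    out[[s$name]] <- if (length(cols)) {
      as.integer(rowSums(burden[, cols, drop = FALSE]))
    } else {
      0L
    }
  }
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Pearson correlation of two per-cluster burden profiles
#'
#' @param profile_a,profile_b equal-length numeric vectors (length >= 3) of
#'   per-cluster mean burden for two gene sets.
#' @return Pearson correlation coefficient.
#' @export
burden_profile_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) fail("profiles differ in length")
  if (length(profile_a) < 3) fail("profiles must have length >= 3")
  if (stats::sd(profile_a) < 1e-12 || stats::sd(profile_b) < 1e-12) {
    fail("zero variance in a burden profile")
  }
  stats::cor(profile_a, profile_b)
}
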