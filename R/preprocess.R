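#' Stratified train/test split
#'
#' Assigns individuals to train/test strata so that, within every level of
#' the stratification label, the test proportion is within one individual of
#' `test_fraction`. Deterministic given `seed`.
#'
#' @param table cohort table with a `case_status` column (or the column named
#'   by `stratify_on`).
#' @param test_fraction proportion in (0,1).
#' @param seed integer seed.
#' @param stratify_on name of the stratification column.
#' @return character vector (`"train"`/`"test"`) aligned to the table rows.
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 1L,
                             stratify_on = "case_status") {
  check_prop(test_fraction, "test_fraction", lo_open = TRUE, hi_open = TRUE)
  strata <- table[[stratify_on]]
  if (is.null(strata)) fail("stratification column '", stratify_on, "' absent")
  if (any(table(strata) < 2)) {
    fail("every stratum needs at least 2 members for a stratified split")
  }
  out <- rep("train", nrow(table))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_test <- round(length(idx) * test_fraction)
      out[sample(idx, n_test)] <- "test"
    }
  })
  out
}

#' Filter features by prevalence in a reference subgroup
#'
#' A feature is retained iff its observed, informative rate among the
#' reference subgroup is at least `min_rate` (boundary inclusive). For binary
#' and count features "informative" means positive/non-zero; for continuous
#' and categorical features any non-missing value counts as observed.
#'
#' @param table cohort table.
#' @param metadata feature metadata (`feature`, `type`).
#' @param min_rate retention threshold in (0, 1].
#' @param reference `"cases"`, `"controls"` or `"all"` — the subgroup whose
#'   rate is thresholded.
#' @return character vector of retained feature names.
#' @export
prevalence_filter <- function(table, metadata, min_rate = 0.01,
                              reference = c("cases", "controls", "all")) {
  reference <- match.arg(reference)
  if (!is.numeric(min_rate) || min_rate <= 0 || min_rate > 1) {
    fail("min_rate must lie in (0, 1]")
  }
  sub <- switch(reference,
    cases = table$case_status == "case",
    controls = table$case_status == "control",
    all = rep(TRUE, nrow(table)))
  if (!any(sub)) fail("reference subgroup '", reference, "' is empty")
  keep <- vapply(seq_len(nrow(metadata)), function(i) {
    f <- metadata$feature[i]
    x <- table[[f]][sub]
    rate <- if (metadata$type[i] %in% c("binary", "count")) {
      mean(!is.na(x) & x > 0)
    } else {
      mean(!is.na(x))
    }
    rate >= min_rate
  }, logical(1))
  metadata$feature[keep]
}

#' Encode a cohort table into a model-ready numeric matrix
#'
#' Continuous and count features are z-scored using moments fitted on the
#' training subset only (no leakage) and missing entries are set to 0 — the
#' post-normalization mean — and flagged in the mask. Binary and categorical
#' features are one-hot encoded and flattened; a missing entry becomes an
#' all-zero group, also flagged. Count features are treated as continuous
#' inputs since the model defines only categorical cross-entropy and
#' continuous squared-error reconstruction losses.
#'
#' @param table cohort table.
#' @param metadata feature metadata (`feature`, `type`, `n_categories`).
#' @param split optional `"train"`/`"test"` assignment from
#'   [stratified_split()]; when `NULL` (full-pipeline runs with no held-out
#'   evaluation) moments are fitted on all individuals.
#' @param features optional subset of features to encode (e.g. the output of
#'   [prevalence_filter()]); default all features in `metadata`.
#' @return an object of class `preprocessed_matrix`: list with `x` (dense
#'   matrix, individuals x encoded columns), `mask` (logical, `TRUE` =
#'   missing), `column_map` (encoded column -> source feature, type, category
#'   index), `center`/`scale` per continuous column, `split`, `ids`.
#' @export
fit_transform <- function(table, metadata, split = NULL, features = NULL) {
  features <- features %||% metadata$feature
  metadata <- metadata[match(features, metadata$feature), , drop = FALSE]
  if (anyNA(metadata$feature)) fail("features absent from metadata")
  split <- split %||% rep("train", nrow(table))
  train <- split == "train"
  if (!any(train)) fail("empty training subset")

  cols <- list()
  map <- list()
  masks <- list()
  centers <- numeric(0)
  scales <- numeric(0)
  for (i in seq_len(nrow(metadata))) {
    f <- metadata$feature[i]
    ty <- metadata$type[i]
    x <- table[[f]]
    if (is.null(x)) fail("feature '", f, "' absent from table")
    miss <- is.na(x)
    if (ty %in% c("continuous", "count")) {
      mu <- mean(x[train & !miss])
      sdv <- stats::sd(x[train & !miss])
      if (!is.finite(sdv) || sdv < 1e-12) {
        fail("feature '", f, "' has zero variance in the training subset")
      }
      z <- (x - mu) / sdv
      z[miss] <- 0
      cols[[length(cols) + 1L]] <- matrix(z, ncol = 1)
      masks[[length(masks) + 1L]] <- matrix(miss, ncol = 1)
      map[[length(map) + 1L]] <- data.frame(
        feature = f, type = "continuous", source_type = ty,
        category = NA_integer_)
      centers <- c(centers, mu)
      scales <- c(scales, sdv)
    } else {
      nc <- if (ty == "binary") 2L else as.integer(metadata$n_categories[i])
      lev <- if (ty == "binary") x + 1L else as.integer(x)
      oh <- matrix(0, length(x), nc)
      obs <- which(!miss)
      if (any(lev[obs] < 1 | lev[obs] > nc)) {
        fail("feature '", f, "' has levels outside 1..", nc)
      }
      oh[cbind(obs, lev[obs])] <- 1
      cols[[length(cols) + 1L]] <- oh
      masks[[length(masks) + 1L]] <- matrix(miss, length(x), nc)
      map[[length(map) + 1L]] <- data.frame(
        feature = f, type = "categorical", source_type = ty,
        category = seq_len(nc))
    }
  }
  x <- do.call(cbind, cols)
  mask <- do.call(cbind, masks)
  column_map <- do.call(rbind, map)
  rownames(column_map) <- NULL
  colnames(x) <- paste0(column_map$feature,
                        ifelse(is.na(column_map$category), "",
                               paste0(".", column_map$category)))
  structure(list(x = x, mask = mask, column_map = column_map,
                 center = centers, scale = scales, split = split,
                 ids = table$id),
            class = "preprocessed_matrix")
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat(sprintf(
    "preprocessed_matrix: %d individuals x %d encoded columns (%d features; %d train / %d test; %.1f%% missing)\n",
    nrow(x$x), ncol(x$x), length(unique(x$column_map$feature)),
    sum(x$split == "train"), sum(x$split == "test"), 100 * mean(x$mask)))
  invisible(x)
}

#' Define cluster-profile aggregation groups
#'
#' @param groups named list; each element a list with `features` (character)
#'   and `rule` in `any` (collapse to a binary any-member-positive
#'   indicator), `sum` (sum member counts), `zscore` (whole-cohort z-score of
#'   a single continuous feature) or `passthrough`.
#' @param metadata feature metadata used for validation.
#' @return an object of class `profile_config`.
#' @export
profile_config <- function(groups, metadata) {
  seen <- character(0)
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (!length(grp$features)) fail("profile group '", g, "' is empty")
    missing <- setdiff(grp$features, metadata$feature)
    if (length(missing)) {
      fail("profile group '", g, "' references unknown feature(s): ",
           paste(missing, collapse = ", "))
    }
    dup <- intersect(grp$features, seen)
    if (length(dup)) {
      fail("feature(s) in more than one profile group: ",
           paste(dup, collapse = ", "))
    }
    seen <- c(seen, grp$features)
    if (!grp$rule %in% c("any", "sum", "zscore", "passthrough")) {
      fail("profile group '", g, "' has unknown rule '", grp$rule, "'")
    }
    types <- metadata$type[match(grp$features, metadata$feature)]
    if (grp$rule == "any" && !all(types %in% c("binary", "categorical"))) {
      fail("profile group '", g, "': rule 'any' needs binary features")
    }
    if (grp$rule == "sum" && !all(types %in% c("count", "binary"))) {
      fail("profile group '", g, "': rule 'sum' needs count features")
    }
    if (grp$rule == "zscore" && !all(types == "continuous")) {
      fail("profile group '", g, "': rule 'zscore' needs continuous features")
    }
  }
  structure(list(groups = groups, metadata = metadata),
            class = "profile_config")
}

#' Build aggregated cluster-profile variables
#'
#' Applies each group's rule: `any` emits 1 iff any member feature is
#' positive (missing members are ignored; all-missing gives `NA`); `sum`
#' emits the sum of member counts over observed members; `zscore` emits
#' whole-cohort z-scores; `passthrough` copies the features unchanged.
#'
#' @param table cohort table.
#' @param config a [profile_config()].
#' @return data.frame of profile variables, one column per group (or per
#'   feature for `passthrough`), plus `id`.
#' @export
build_profiles <- function(table, config) {
  stopifnot(inherits(config, "profile_config"))
  out <- data.frame(id = table$id, stringsAsFactors = FALSE)
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    sub <- as.matrix(table[, grp$features, drop = FALSE])
    if (grp$rule == "any") {
      val <- apply(sub, 1, function(r) {
        if (all(is.na(r))) NA_real_ else as.numeric(any(r > 0, na.rm = TRUE))
      })
      out[[g]] <- val
    } else if (grp$rule == "sum") {
      out[[g]] <- rowSums(sub, na.rm = TRUE)
    } else if (grp$rule == "zscore") {
      for (f in grp$features) {
        x <- table[[f]]
        out[[if (length(grp$features) == 1L) g else paste0(g, ".", f)]] <-
          (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
      }
    } else { # passthrough
      for (f in grp$features) out[[f]] <- table[[f]]
    }
  }
  out
}
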