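#' One-vs-rest indicator for a cluster
#'
#' @param assignment integer/character label vector.
#' @param cluster_id the cluster compared against the rest combined.
#' @return 0/1 integer vector (1 = member).
#' @export
one_vs_rest_indicator <- function(assignment, cluster_id) {
  ind <- as.integer(assignment == cluster_id)
  if (!any(ind == 1L)) fail("cluster '", cluster_id, "' is empty")
  ind
}

#' Minimum-event filter for binary and count outcomes
#'
#' A comparison is excluded when the number of events (positives for binary
#' outcomes, non-zero observations for counts) is below `min_events` in
#' either the cluster or the remainder; the filter never applies to
#' continuous outcomes.
#'
#' @param outcome numeric outcome vector.
#' @param indicator one-vs-rest indicator.
#' @param min_events threshold (default 5).
#' @param both_sides require `min_events` on both sides (default) or only in
#'   the cluster.
#' @return list: `include` (logical), `events_in`, `events_out`.
#' @export
event_filter <- function(outcome, indicator, min_events = 5L,
                         both_sides = TRUE) {
  ev <- !is.na(outcome) & outcome > 0
  n_in <- sum(ev & indicator == 1L)
  n_out <- sum(ev & indicator == 0L)
  include <- n_in >= min_events && (!both_sides || n_out >= min_events)
  list(include = include, events_in = n_in, events_out = n_out)
}

## Shared scaffolding: design data frame and a fitted-model row extractor.
make_design <- function(outcome, indicator, covariates) {
  df <- data.frame(.y = outcome, .ind = indicator)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(outcome))
    if (anyNA(covariates)) fail("missing covariate values among tested individuals")
    df <- cbind(df, covariates)
  }
  df
}

result_row <- function(outcome_name, cluster_id, family, effect_type,
                       effect = NA_real_, std_avg = NA_real_, p = NA_real_,
                       n_events = NA_integer_, excluded = FALSE,
                       reason = "") {
  data.frame(outcome = outcome_name, cluster = as.character(cluster_id),
             family = family, effect_type = effect_type, effect = effect,
             std_avg = std_avg, p = p, n_events = n_events,
             excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Logistic one-vs-rest enrichment test
#'
#' Maximum-likelihood logistic regression of a binary outcome on the cluster
#' indicator plus covariates; the effect is the odds ratio
#' `exp(coefficient)` with a Wald p-value. Perfect separation is flagged and
#' the effect reported as non-estimable rather than as a huge finite number.
#'
#' @param outcome 0/1 outcome vector.
#' @param indicator one-vs-rest indicator from [one_vs_rest_indicator()].
#' @param covariates optional data.frame of adjustment covariates.
#' @param outcome_name,cluster_id labels carried into the result.
#' @return one-row data.frame (see [enrichment_scan()] for columns).
#' @export
test_binary <- function(outcome, indicator, covariates = NULL,
                        outcome_name = "outcome", cluster_id = "1") {
  df <- make_design(outcome, indicator, covariates)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!".ind" %in% rownames(co)) {
    return(result_row(outcome_name, cluster_id, "logistic", "OR",
                      n_events = sum(outcome > 0, na.rm = TRUE),
                      excluded = TRUE, reason = "indicator aliased"))
  }
  b <- co[".ind", "Estimate"]
  if (sep_warn || abs(b) > 10) {
    return(result_row(outcome_name, cluster_id, "logistic", "OR",
                      n_events = sum(outcome > 0, na.rm = TRUE),
                      excluded = TRUE, reason = "perfect separation"))
  }
  result_row(outcome_name, cluster_id, "logistic", "OR",
             effect = exp(b), p = co[".ind", "Pr(>|z|)"],
             n_events = sum(outcome[indicator == 1L] > 0, na.rm = TRUE))
}

#' Linear one-vs-rest enrichment test
#'
#' Ordinary least squares of a continuous outcome on the cluster indicator
#' plus covariates; the effect is the indicator coefficient (beta). The
#' standardized average — the mean of the cohort-z-scored outcome within the
#' cluster — is reported alongside.
#'
#' @inheritParams test_binary
#' @param outcome continuous outcome vector.
#' @return one-row data.frame.
#' @export
test_continuous <- function(outcome, indicator, covariates = NULL,
                            outcome_name = "outcome", cluster_id = "1") {
  if (stats::sd(outcome, na.rm = TRUE) < 1e-12) {
    fail("outcome '", outcome_name, "' has zero variance")
  }
  df <- make_design(outcome, indicator, covariates)
  fit <- stats::lm(.y ~ ., data = df)
  co <- summary(fit)$coefficients
  z <- (outcome - mean(outcome, na.rm = TRUE)) / stats::sd(outcome, na.rm = TRUE)
  std_avg <- mean(z[indicator == 1L], na.rm = TRUE)
  if (!".ind" %in% rownames(co)) {
    # constant indicator (e.g. the cluster is the whole cohort): the contrast
    # is undefined but the standardized average still is
    return(result_row(outcome_name, cluster_id, "linear", "beta",
                      std_avg = std_avg, excluded = TRUE,
                      reason = "indicator aliased"))
  }
  result_row(outcome_name, cluster_id, "linear", "beta",
             effect = co[".ind", "Estimate"],
             std_avg = std_avg,
             p = co[".ind", "Pr(>|t|)"],
             n_events = NA_integer_)
}

#' Cameron-Trivedi overdispersion test
#'
#' Auxiliary-regression test of the Poisson mean-variance identity: with
#' `mu` the Poisson fitted values, regresses `((y - mu)^2 - y) / mu` on `mu`
#' without intercept and tests the slope against the one-sided
#' overdispersion alternative.
#'
#' @param outcome count outcome.
#' @param indicator,covariates design as in [test_count()].
#' @return list: `p_value`, `alpha_hat` (auxiliary slope), `defined`.
#' @export
dispersion_test <- function(outcome, indicator, covariates = NULL) {
  if (all(outcome == 0, na.rm = TRUE) ||
      stats::sd(outcome, na.rm = TRUE) < 1e-12) {
    return(list(p_value = NA_real_, alpha_hat = NA_real_, defined = FALSE))
  }
  df <- make_design(outcome, indicator, covariates)
  fit <- stats::glm(.y ~ ., data = df, family = stats::poisson())
  mu <- stats::fitted(fit)
  aux_y <- ((df$.y - mu)^2 - df$.y) / mu
  aux <- stats::lm(aux_y ~ mu - 1)
  co <- summary(aux)$coefficients
  z <- co["mu", "t value"]
  list(p_value = stats::pnorm(z, lower.tail = FALSE),
       alpha_hat = co["mu", "Estimate"], defined = TRUE)
}

#' Count one-vs-rest enrichment test with overdispersion switching
#'
#' Poisson log-link regression of a count outcome on the cluster indicator
#' plus covariates; when the dispersion test detects overdispersion
#' (p < `dispersion_alpha`) the model is refit as negative binomial with
#' ML-estimated size. The effect is the rate ratio `exp(coefficient)`. NB
#' non-convergence falls back to Poisson with a warning flag in `reason`.
#'
#' @inheritParams test_binary
#' @param outcome non-negative count outcome.
#' @param dispersion_alpha switch threshold (default 0.05).
#' @return one-row data.frame; `family` records which model was used.
#' @export
test_count <- function(outcome, indicator, covariates = NULL,
                       outcome_name = "outcome", cluster_id = "1",
                       dispersion_alpha = 0.05) {
  df <- make_design(outcome, indicator, covariates)
  disp <- dispersion_test(outcome, indicator, covariates)
  family <- "poisson"
  reason <- ""
  if (isTRUE(disp$defined) && !is.na(disp$p_value) &&
      disp$p_value < dispersion_alpha) {
    nb <- tryCatch(
      suppressWarnings(MASS::glm.nb(.y ~ ., data = df)),
      error = function(e) NULL)
    if (!is.null(nb) && nb$converged) {
      family <- "negbin"
      fit <- nb
    } else {
      reason <- "NB fit did not converge; Poisson retained"
      fit <- stats::glm(.y ~ ., data = df, family = stats::poisson())
    }
  } else {
    fit <- stats::glm(.y ~ ., data = df, family = stats::poisson())
  }
  co <- summary(fit)$coefficients
  result_row(outcome_name, cluster_id, family, "RR",
             effect = exp(co[".ind", "Estimate"]),
             p = co[".ind", "Pr(>|z|)"],
             n_events = sum(outcome[indicator == 1L] > 0, na.rm = TRUE),
             reason = reason)
}

#' Bonferroni and Benjamini-Hochberg adjustment within a family
#'
#' `NaN`/`NA` p-values are excluded from the family size and flagged with
#' `NA` adjusted values.
#'
#' @param p raw p-values in [0, 1].
#' @param family_label label recorded with the adjustment (informational).
#' @return data.frame: `p`, `p_bonferroni`, `q_bh`, `family`.
#' @export
adjust_pvalues <- function(p, family_label = "family") {
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) fail("p-values must lie in [0, 1]")
  bonf <- bh <- rep(NA_real_, length(p))
  bonf[ok] <- stats::p.adjust(p[ok], method = "bonferroni")
  bh[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(p = p, p_bonferroni = bonf, q_bh = bh, family = family_label)
}

stars_for <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' One-vs-rest enrichment scan over outcomes and clusters
#'
#' Runs the family-appropriate test (logistic for binary, linear for
#' continuous, Poisson/negative-binomial for counts) for every
#' (outcome x cluster) pair, applies the minimum-event filter to binary and
#' count outcomes, and adjusts p-values within the declared multiplicity
#' family (Bonferroni and Benjamini-Hochberg, computed over the whole scan).
#' Significance stars at 0.05 / 0.01 / 0.001 are reported on the Bonferroni
#' scale (`stars_bonf`) and on the FDR scale separately (`stars_fdr`). Every
#' pair appears exactly once, either with results or an exclusion reason.
#'
#' @param outcomes data.frame of outcome columns (no id column), aligned to
#'   `assignment`.
#' @param outcome_types character vector (`"binary"`, `"continuous"`,
#'   `"count"`) aligned to `names(outcomes)`.
#' @param assignment cluster label vector.
#' @param covariates optional covariate data.frame.
#' @param family_label multiplicity-family label (clinical / PGS /
#'   rare-variant analyses are corrected separately).
#' @param min_events minimum-event threshold.
#' @return data.frame in long format: outcome, cluster, family, effect_type,
#'   effect, std_avg, p, p_bonf, q_fdr, n_events, stars_bonf, stars_fdr,
#'   excluded, reason.
#' @export
enrichment_scan <- function(outcomes, outcome_types, assignment,
                            covariates = NULL, family_label = "clinical",
                            min_events = 5L) {
  stopifnot(length(outcome_types) == ncol(outcomes))
  if (nrow(outcomes) != length(assignment)) {
    fail("outcomes and assignment are misaligned")
  }
  clusters <- sort(unique(assignment))
  rows <- list()
  for (j in seq_along(outcomes)) {
    nm <- names(outcomes)[j]
    ty <- outcome_types[j]
    y <- outcomes[[j]]
    for (cl in clusters) {
      ind <- one_vs_rest_indicator(assignment, cl)
      ok <- !is.na(y)
      res <- if (ty %in% c("binary", "count")) {
        ef <- event_filter(y[ok], ind[ok], min_events)
        if (!ef$include) {
          result_row(nm, cl, if (ty == "binary") "logistic" else "poisson",
                     if (ty == "binary") "OR" else "RR",
                     n_events = ef$events_in, excluded = TRUE,
                     reason = sprintf("<%d events", min_events))
        } else if (ty == "binary") {
          test_binary(y[ok], ind[ok],
                      if (is.null(covariates)) NULL else
                        covariates[ok, , drop = FALSE], nm, cl)
        } else {
          test_count(y[ok], ind[ok],
                     if (is.null(covariates)) NULL else
                       covariates[ok, , drop = FALSE], nm, cl)
        }
      } else {
        test_continuous(y[ok], ind[ok],
                        if (is.null(covariates)) NULL else
                          covariates[ok, , drop = FALSE], nm, cl)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, family_label)
  out$p_bonf <- adj$p_bonferroni
  out$q_fdr <- adj$q_bh
  out$stars_bonf <- stars_for(out$p_bonf)
  out$stars_fdr <- stars_for(out$q_fdr)
  out$family_label <- family_label
  out
}

#' Per-cluster case/control composition
#'
#' For each cluster: the number of cases and controls it contains and the
#' percentage of all cases / all controls falling in it. Percentages are
#' reported with one decimal in `pct_cases_label` / `pct_controls_label`;
#' full precision is kept in the numeric columns.
#'
#' @param assignment cluster label vector.
#' @param case_status `"case"`/`"control"` vector aligned to `assignment`.
#' @return data.frame: cluster, n, n_cases, n_controls, pct_cases,
#'   pct_controls and their one-decimal labels.
#' @export
cluster_composition <- function(assignment, case_status) {
  if (length(assignment) != length(case_status)) {
    fail("assignment and case_status are misaligned")
  }
  total_cases <- sum(case_status == "case")
  total_controls <- sum(case_status == "control")
  clusters <- sort(unique(assignment))
  out <- do.call(rbind, lapply(clusters, function(cl) {
    inc <- assignment == cl
    nc <- sum(inc & case_status == "case")
    nk <- sum(inc & case_status == "control")
    data.frame(cluster = as.character(cl), n = sum(inc),
               n_cases = nc, n_controls = nk,
               pct_cases = if (total_cases > 0) 100 * nc / total_cases else 0,
               pct_controls = if (total_controls > 0) 100 * nk / total_controls else 0,
               stringsAsFactors = FALSE)
  }))
  out$pct_cases_label <- sprintf("%.1f%%", out$pct_cases)
  out$pct_controls_label <- sprintf("%.1f%%", out$pct_controls)
  out
}
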