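## Internal helpers for the validity-index panel. All indices operate on a
## precomputed distance matrix and/or k-means partitions over the k range.

within_ss <- function(x, labels) {
  sum(vapply(unique(labels), function(c) {
    xs <- x[labels == c, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

index_calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  w <- within_ss(x, labels)
  tot <- sum(sweep(x, 2, colMeans(x))^2)
  b <- tot - w
  (b / (k - 1)) / (w / (n - k))
}

index_davies_bouldin <- function(x, labels) {
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(c) colMeans(x[labels == c, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(cls), function(i) {
    xs <- x[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, cent[i, ])^2)))
  }, numeric(1))
  mean(vapply(seq_along(cls), function(i) {
    max(vapply(seq_along(cls)[-i], function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

index_dunn <- function(d, labels) {
  dm <- as.matrix(d)
  cls <- sort(unique(labels))
  min_between <- Inf; max_within <- 0
  for (i in seq_along(cls)) {
    wi <- labels == cls[i]
    dw <- dm[wi, wi, drop = FALSE]
    if (sum(wi) > 1) max_within <- max(max_within, max(dw))
    for (j in seq_along(cls)) {
      if (j <= i) next
      min_between <- min(min_between, min(dm[wi, labels == cls[j],
                                             drop = FALSE]))
    }
  }
  if (max_within == 0) return(Inf)
  min_between / max_within
}

index_c <- function(d, labels) {
  dv <- as.vector(stats::as.dist(d))
  dm <- as.matrix(d)
  sw <- 0; nw <- 0L
  for (c in unique(labels)) {
    wi <- which(labels == c)
    if (length(wi) > 1) {
      sw <- sw + sum(stats::as.dist(dm[wi, wi]))
      nw <- nw + length(wi) * (length(wi) - 1L) / 2L
    }
  }
  if (nw == 0) return(NA_real_)
  srt <- sort(dv)
  smin <- sum(srt[seq_len(nw)])
  smax <- sum(srt[seq(length(srt) - nw + 1L, length(srt))])
  if (smax - smin < 1e-12) return(NA_real_)
  (sw - smin) / (smax - smin)
}

#' Cluster-number validity panel
#'
#' Evaluates a defined panel of validity indices over a k range, each with
#' its standard best-k rule, and returns the majority-vote k (ties broken
#' toward smaller k). The panel comprises mean silhouette width (max),
#' Calinski-Harabasz (max), Davies-Bouldin (min), Dunn (max), the gap
#' statistic (first-SE-max rule), Hartigan's rule (smallest k with index
#' <= 10, else max drop), Ball-Hall (largest successive drop) and the
#' C-index (min). A `weak_structure` flag is raised when even the best mean
#' silhouette width is below 0.25.
#'
#' @param x numeric matrix.
#' @param k_range integer vector of candidate k in `[2, n - 1]`.
#' @param seed integer seed.
#' @param n_init k-means restarts per k.
#' @param gap_b reference sets for the gap statistic (default 25).
#' @return list: `votes` (data.frame index / best_k), `majority_k`,
#'   `weak_structure`, `per_k` (data.frame of index values per k).
#' @export
validity_panel <- function(x, k_range, seed = 1L, n_init = 5L, gap_b = 25L) {
  x <- as.matrix(x)
  if (!length(k_range)) fail("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(x) - 1) {
    fail("k_range must lie within [2, n - 1]")
  }
  d <- stats::dist(x)
  fits <- lapply(k_range, function(k) {
    kmeans_fit(x, k, seed = derive_seed(seed, 300L + k), n_init = n_init)
  })
  names(fits) <- as.character(k_range)
  # k_range extended downward by one for difference-based rules
  k_ext <- c(max(1L, min(k_range) - 1L), k_range, max(k_range) + 1L)
  w_ext <- vapply(k_ext, function(k) {
    if (k == 1) {
      sum(sweep(x, 2, colMeans(x))^2)
    } else if (as.character(k) %in% names(fits)) {
      fits[[as.character(k)]]$inertia
    } else {
      kmeans_fit(x, k, seed = derive_seed(seed, 300L + k),
                 n_init = n_init)$inertia
    }
  }, numeric(1))
  names(w_ext) <- as.character(k_ext)

  per_k <- data.frame(k = k_range)
  per_k$silhouette <- vapply(fits, function(f) {
    mean(cluster::silhouette(f$cluster, d)[, "sil_width"])
  }, numeric(1))
  per_k$calinski_harabasz <- vapply(fits, function(f) {
    index_calinski_harabasz(x, f$cluster)
  }, numeric(1))
  per_k$davies_bouldin <- vapply(fits, function(f) {
    index_davies_bouldin(x, f$cluster)
  }, numeric(1))
  per_k$dunn <- vapply(fits, function(f) index_dunn(d, f$cluster), numeric(1))
  per_k$c_index <- vapply(fits, function(f) index_c(d, f$cluster), numeric(1))
  n <- nrow(x)
  per_k$hartigan <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    (w_ext[as.character(k)] / w_ext[as.character(k + 1L)] - 1) * (n - k - 1)
  }, numeric(1))
  ball <- w_ext[as.character(k_ext[k_ext >= 1 & k_ext <= max(k_range)])] /
    as.numeric(names(w_ext)[k_ext >= 1 & k_ext <= max(k_range)])
  per_k$ball_hall_drop <- vapply(k_range, function(k) {
    prev <- as.character(k - 1L)
    if (!prev %in% names(ball)) return(NA_real_)
    ball[[prev]] - ball[[as.character(k)]]
  }, numeric(1))

  gap <- with_seed(derive_seed(seed, 399L), {
    cluster::clusGap(x, FUN = function(xx, k) {
      list(cluster = kmeans_fit(xx, k, seed = derive_seed(seed, 300L + k),
                                n_init = n_init)$cluster)
    }, K.max = max(k_range), B = gap_b, verbose = FALSE)
  })
  gap_k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                          method = "firstSEmax")
  gap_k <- k_range[which.min(abs(k_range - gap_k))]

  best_of <- function(v, rule) {
    if (all(is.na(v))) return(NA_integer_)
    k_range[switch(rule, max = which.max(v), min = which.min(v))]
  }
  hart <- per_k$hartigan
  hart_k <- if (any(hart <= 10, na.rm = TRUE)) {
    k_range[which(hart <= 10)[1]]
  } else {
    k_range[which.max(-diff(c(Inf, hart)))]
  }
  votes <- data.frame(
    index = c("silhouette", "calinski_harabasz", "davies_bouldin", "dunn",
              "gap", "hartigan", "ball_hall", "c_index"),
    best_k = c(best_of(per_k$silhouette, "max"),
               best_of(per_k$calinski_harabasz, "max"),
               best_of(per_k$davies_bouldin, "min"),
               best_of(per_k$dunn, "max"),
               gap_k,
               hart_k,
               best_of(per_k$ball_hall_drop, "max"),
               best_of(per_k$c_index, "min")))
  tab <- table(votes$best_k)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(votes = votes, majority_k = min(winners),
       weak_structure = max(per_k$silhouette, na.rm = TRUE) < 0.25,
       per_k = per_k)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal consensus-matrix entries falling inside the
#' ambiguity window; low PAC indicates stable clustering.
#'
#' @param consensus consensus matrix from [consensus_cluster()].
#' @param window ambiguity window (default (0.1, 0.9), exclusive).
#' @return scalar PAC in [0, 1].
#' @export
pac_statistic <- function(consensus, window = c(0.1, 0.9)) {
  off <- consensus[lower.tri(consensus)]
  mean(off > window[1] & off < window[2])
}

#' Monte-Carlo reference significance of cluster numbers
#'
#' For each candidate k, compares the real data's PAC with a null
#' distribution of PACs from datasets simulated under spatial homogeneity: a
#' multivariate normal matching the real data's mean and principal-component
#' eigen-structure (eigenvalues floored at 1e-8 against singular
#' covariance). The p-value uses the add-one estimator
#' `p = (1 + #\{null PAC <= real PAC\}) / (n_null + 1)`.
#'
#' @param x numeric matrix.
#' @param k_range candidate cluster numbers.
#' @param n_null null reference datasets (>= 10; default 25).
#' @param runs consensus k-means runs per dataset.
#' @param seed integer seed.
#' @param n_init restarts per k-means run. The default of 1 is deliberate:
#'   the consensus variability across differently seeded single runs is the
#'   signal PAC measures; multi-restart runs collapse that variability on
#'   null data and drain the test's power.
#' @param window PAC ambiguity window.
#' @return data.frame: `k`, `pac`, `p_value`, plus the null PACs as the
#'   `null_pac` attribute (matrix k x n_null).
#' @export
mc_reference_significance <- function(x, k_range, n_null = 25L, runs = 25L,
                                      seed = 1L, n_init = 1L,
                                      window = c(0.1, 0.9)) {
  x <- as.matrix(x)
  if (n_null < 10) fail("n_null must be >= 10")
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-8)
  rot <- eg$vectors %*% diag(sqrt(ev), p)
  sim_null <- function(s) {
    z <- with_seed(s, matrix(stats::rnorm(n * p), n, p))
    sweep(z %*% t(rot), 2, mu, "+")
  }
  real_pac <- vapply(k_range, function(k) {
    cc <- consensus_cluster(x, k, runs = runs,
                            seed = derive_seed(seed, 400L + k),
                            n_init = n_init)
    pac_statistic(cc$consensus, window)
  }, numeric(1))
  null_pac <- matrix(NA_real_, length(k_range), n_null)
  for (b in seq_len(n_null)) {
    xb <- sim_null(derive_seed(seed, 500L + b))
    null_pac[, b] <- vapply(k_range, function(k) {
      cc <- consensus_cluster(xb, k, runs = runs,
                              seed = derive_seed(seed, 600L + 31L * b + k),
                              n_init = n_init)
      pac_statistic(cc$consensus, window)
    }, numeric(1))
  }
  p_value <- vapply(seq_along(k_range), function(i) {
    (1 + sum(null_pac[i, ] <= real_pac[i])) / (n_null + 1)
  }, numeric(1))
  out <- data.frame(k = k_range, pac = real_pac, p_value = p_value)
  attr(out, "null_pac") <- null_pac
  out
}
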