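#' Hopkins statistic for clusterability
#'
#' `H = sum(w) / (sum(u) + sum(w))` where `w` are nearest-neighbour distances
#' from `m` sampled real points to the remaining real points and `u` are
#' nearest-neighbour distances from `m` uniform points (drawn in the data's
#' bounding box) to the real points. Under spatial randomness `H ~ Beta(m, m)`
#' with mean 0.5; values near 0 indicate clustered data (the convention used
#' throughout this package); the complement `1 - H` is reported alongside to
#' avoid any ambiguity between conventions.
#'
#' @param x numeric matrix (individuals x dimensions).
#' @param m number of probe points (default `min(n - 1, ceiling(0.1 n))`).
#' @param seed integer seed.
#' @return list: `H`, `complement` (= 1 - H), `m`.
#' @export
hopkins_statistic <- function(x, m = NULL, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) fail("need at least 2 rows")
  m <- m %||% max(1L, min(n - 1L, ceiling(0.1 * n)))
  if (m >= n) fail("m must be smaller than the number of rows")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (all(hi - lo < 1e-12)) fail("zero-extent bounding box")
  with_seed(seed, {
    probes <- sample.int(n, m)
    # w: NN distance from each sampled real point to the other real points
    w <- vapply(probes, function(i) {
      d2 <- rowSums(sweep(x[-i, , drop = FALSE], 2, x[i, ])^2)
      sqrt(min(d2))
    }, numeric(1))
    u_pts <- matrix(stats::runif(m * ncol(x), min = rep(lo, each = m),
                                 max = rep(hi, each = m)), m, ncol(x))
    u <- vapply(seq_len(m), function(i) {
      d2 <- rowSums(sweep(x, 2, u_pts[i, ])^2)
      sqrt(min(d2))
    }, numeric(1))
    H <- sum(w) / (sum(u) + sum(w))
    list(H = H, complement = 1 - H, m = m)
  })
}

## k-means++ seeding: spread initial centers by D^2-weighted sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  if (k > 1) for (c in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) < 1e-300) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = p)
    }
    centers[c, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[c, ])^2))
  }
  centers
}

#' k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations (via `stats::kmeans`) from k-means++ initial centers,
#' best of `n_init` restarts by inertia (total within-cluster sum of
#' squares). Deterministic given `seed`. A run that collapses to an empty
#' cluster is re-seeded internally; an error is raised only if this
#' persists.
#'
#' @param x numeric matrix.
#' @param k number of clusters (<= n).
#' @param seed integer seed.
#' @param n_init restarts (default 10).
#' @return list: `cluster` (labels in 1..k), `centers`, `inertia`, `k`.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_init = 10L) {
  x <- as.matrix(x)
  if (k > nrow(x)) fail("k exceeds the number of rows")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- NULL
      for (attempt in 1:10) {
        centers <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          stats::kmeans(x, centers = centers, iter.max = 100L,
                        algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && length(unique(fit$cluster)) == k) break
        fit <- NULL
      }
      if (is.null(fit)) {
        if (k == nrow(x)) { # degenerate: every point its own cluster
          fit <- list(cluster = seq_len(k), centers = x, tot.withinss = 0)
        } else {
          fail("k-means produced persistent empty clusters (k = ", k, ")")
        }
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(cluster = unname(best$cluster), centers = best$centers,
         inertia = best$tot.withinss, k = k)
  })
}

#' Consensus k-means clustering
#'
#' Runs k-means `runs` times with distinct derived seeds and identical
#' parameters, builds the consensus matrix `C` of pairwise co-clustering
#' frequencies, then derives the final assignment by reapplying k-means with
#' the same `k` to the rows of `C`.
#'
#' @param x numeric matrix.
#' @param k number of clusters.
#' @param runs number of k-means runs (default 100).
#' @param seed integer seed.
#' @param n_init restarts within each run.
#' @param max_n memory guard: `C` is n x n; exceeding `max_n` rows requires
#'   raising this cap explicitly.
#' @return list: `consensus` (n x n matrix), `assignment` (final labels),
#'   `runs_labels` (matrix n x runs of per-run labels), `k`, `runs`.
#' @export
consensus_cluster <- function(x, k, runs = 100L, seed = 1L, n_init = 3L,
                              max_n = 10000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (runs < 1) fail("runs must be >= 1")
  if (n > max_n) {
    fail("n = ", n, " exceeds the consensus-matrix guard (max_n = ", max_n,
         "); raise max_n to opt in")
  }
  C <- matrix(0, n, n)
  labels <- matrix(NA_integer_, n, runs)
  for (r in seq_len(runs)) {
    fit <- kmeans_fit(x, k, seed = derive_seed(seed, 200L + r),
                      n_init = n_init)
    labels[, r] <- fit$cluster
    same <- outer(fit$cluster, fit$cluster, "==")
    C <- C + same
  }
  C <- C / runs
  final <- kmeans_fit(C, k, seed = derive_seed(seed, 199L), n_init = n_init)
  list(consensus = C, assignment = final$cluster, runs_labels = labels,
       k = k, runs = runs)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model; 1 for identical partitions (up to label renaming), about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) fail("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  tot <- comb2(n)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Pairwise stability of repeated clustering runs
#'
#' ARI for all pairs of runs, with the median as the headline stability
#' figure.
#'
#' @param labels_list list (or matrix columns) of label vectors from
#'   repeated runs.
#' @return list: `median`, `ari` (vector over run pairs).
#' @export
pairwise_stability <- function(labels_list) {
  if (is.matrix(labels_list)) {
    labels_list <- lapply(seq_len(ncol(labels_list)),
                          function(j) labels_list[, j])
  }
  r <- length(labels_list)
  if (r < 2) fail("need at least 2 runs")
  ari <- c()
  for (a in seq_len(r - 1L)) {
    for (b in seq(a + 1L, r)) {
      ari <- c(ari, adjusted_rand_index(labels_list[[a]], labels_list[[b]]))
    }
  }
  list(median = stats::median(ari), ari = ari)
}
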