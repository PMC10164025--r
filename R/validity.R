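#' Correlation-adapted cluster quality indices
#'
#' Quality of a single cluster and of a whole partition, on the
#' absolute-correlation similarity scale. For cluster \eqn{C_m},
#' \deqn{QI_c(m) = 100\Big[\frac{1}{|C_m|^2 - |C_m|}\sum_{i \ne j \in C_m} |r_{ij}|
#'   - \frac{1}{|C_m||C_{-m}|}\sum_{i \in C_m}\sum_{j \in C_{-m}} |r_{ij}|\Big],}
#' the difference between the mean within-cluster similarity and the mean
#' similarity to everything outside the cluster (\eqn{C_{-m}} includes the
#' others pool), scaled by 100 and hence bounded in \eqn{[-100, 100]}.
#' The partition-level `qi()` is the size-weighted average
#' \eqn{\sum_m (|C_m|/n)\, QI_c(m)} over clusters; components in the others
#' pool carry no weight, so heavy use of the outlier pool is penalized.
#'
#' `qic_hat()`/`qi_hat()` are the local-density variants used as the
#' clustering GA's fitness: the between term averages only the
#' \eqn{|C_m| \cdot F_c} largest between-cluster similarities (capped at the
#' number of available pairs), so a cluster is judged against its nearest
#' neighbours rather than the whole pool. With `fc` large enough the two
#' variants coincide.
#'
#' A singleton cluster has no within-cluster pairs; called directly on one,
#' `qic()`/`qic_hat()` return 0 with a warning (the clustering pipeline
#' folds singletons into the others pool before scoring).
#'
#' @param sim Similarity matrix from [to_similarity()].
#' @param assignment Integer partition vector (0 = others; see
#'   [as_partition()]).
#' @param m Cluster label to score.
#' @param fc Local-density regularization factor (default 10): each
#'   cluster's between term uses its `|C_m| * fc` strongest outside
#'   similarities.
#' @return `qic()`/`qic_hat()` return one scalar; `qi()`/`qi_hat()` return
#'   the size-weighted aggregate.
#' @examples
#' syn <- generate_ic_set(synthetic_spec(cluster_sizes = c(5, 5),
#'                                       outlier_count = 2, rng_seed = 1))
#' sim <- to_similarity(compute_correlation_matrix(syn$ws))
#' qi(sim, syn$partition)
#' qi_hat(sim, syn$partition, fc = 2)
#' @export
qic <- function(sim, assignment, m) {
  z <- as_partition_like(assignment, sim)
  members <- which(z == m)
  if (length(members) < 2L) {
    warning("cluster ", m, " has fewer than 2 members; qic is 0")
    return(0)
  }
  w <- within_mean(sim, members)
  outside <- which(z != m)
  b <- if (length(outside)) mean(sim[members, outside]) else 0
  100 * (w - b)
}

#' @rdname qic
#' @export
qi <- function(sim, assignment) {
  z <- as_partition_like(assignment, sim)
  labs <- cluster_labels(z)
  if (!length(labs)) {
    stop_icclust("partition has no clusters; qi is undefined",
                 class = "icclust_no_cluster_error")
  }
  n <- length(z)
  sum(vapply(labs, function(l) sum(z == l) / n * qic(sim, z, l), 0))
}

#' @rdname qic
#' @export
qic_hat <- function(sim, assignment, m, fc = 10L) {
  if (fc < 1) {
    stop_icclust("fc must be >= 1", class = "icclust_validation_error")
  }
  z <- as_partition_like(assignment, sim)
  members <- which(z == m)
  if (length(members) < 2L) {
    warning("cluster ", m, " has fewer than 2 members; qic_hat is 0")
    return(0)
  }
  w <- within_mean(sim, members)
  outside <- which(z != m)
  b <- top_between_mean(sim, members, outside, fc)
  100 * (w - b)
}

#' @rdname qic
#' @export
qi_hat <- function(sim, assignment, fc = 10L) {
  z <- as_partition_like(assignment, sim)
  labs <- cluster_labels(z)
  if (!length(labs)) {
    stop_icclust("partition has no clusters; qi_hat is undefined",
                 class = "icclust_no_cluster_error")
  }
  n <- length(z)
  sum(vapply(labs, function(l) sum(z == l) / n * qic_hat(sim, z, l, fc), 0))
}

within_mean <- function(sim, members) {
  m <- length(members)
  (sum(sim[members, members]) - sum(diag(sim)[members])) / (m^2 - m)
}

top_between_mean <- function(sim, members, outside, fc) {
  if (!length(outside)) return(0)
  v <- as.numeric(sim[members, outside])
  p <- min(length(members) * fc, length(v))
  vs <- sort(v, decreasing = TRUE)
  mean(vs[seq_len(p)])
}

as_partition_like <- function(assignment, sim) {
  z <- if (is.double(assignment)) as.integer(round(assignment)) else assignment
  if (length(z) != nrow(sim)) {
    stop_icclust("assignment length ", length(z),
                 " does not match similarity dimension ", nrow(sim),
                 class = "icclust_validation_error")
  }
  z
}

#' Correlation-based silhouette values
#'
#' For each clustered component i (others excluded), `a_i` is its average
#' similarity to the rest of its cluster and `b_i` the largest average
#' similarity to any other cluster; the silhouette is
#' \eqn{s_i = (a_i - b_i)/\max(a_i, b_i) \in [-1, 1]}. As defined here the
#' `a_i` average divides by the full cluster size \eqn{|C_m|} (the
#' `denominator = "as_printed"` default); the conventional divisor
#' \eqn{|C_m| - 1} is available via `denominator = "standard"`. `sh_index()`
#' is the mean silhouette over clustered components.
#'
#' @inheritParams qic
#' @param denominator `"as_printed"` (divide `a_i` by `|C_m|`) or
#'   `"standard"` (divide by `|C_m| - 1`).
#' @return `silhouette_values()`: named numeric vector of \eqn{s_i} for
#'   components not in the others pool; `sh_index()`: their mean.
#' @export
silhouette_values <- function(sim, assignment,
                              denominator = c("as_printed", "standard")) {
  denominator <- match.arg(denominator)
  z <- as_partition_like(assignment, sim)
  labs <- cluster_labels(z)
  if (length(labs) < 2L) {
    stop_icclust("silhouette needs at least 2 clusters",
                 class = "icclust_no_cluster_error")
  }
  memb <- cluster_members(z)
  idx <- which(z > 0L)
  s <- vapply(idx, function(i) {
    own <- memb[[as.character(z[i])]]
    own_other <- setdiff(own, i)
    denom <- if (denominator == "as_printed") length(own) else length(own_other)
    a <- if (length(own_other)) sum(sim[i, own_other]) / denom else 0
    b <- max(vapply(labs[labs != z[i]], function(l) {
      mean(sim[i, memb[[as.character(l)]]])
    }, 0))
    mx <- max(a, b)
    if (mx == 0) 0 else (a - b) / mx
  }, 0)
  names(s) <- idx
  s
}

#' @rdname silhouette_values
#' @export
sh_index <- function(sim, assignment,
                     denominator = c("as_printed", "standard")) {
  mean(silhouette_values(sim, assignment, denominator))
}

#' Inverted Davies-Bouldin index on the correlation scale
#'
#' Compactness of cluster m is \eqn{d_m}, the mean absolute correlation of
#' its members with its centroid; separation between clusters m and n is
#' the absolute correlation \eqn{|r_{MN}|} of their centroid maps. Because
#' large values mean "close" here, the classical ratio is inverted:
#' \deqn{DB_m = \max_{n \ne m} \frac{|r_{MN}|}{d_m + d_n}, \qquad
#'   DB = \frac{1}{k}\sum_m DB_m,} and smaller is better (0 when all
#' centroid pairs are orthogonal). Centroids are computed with the exact
#' polarity solver for clusters up to `brute_cap` members and the genetic
#' solver above, so the index is deterministic given `rng_seed`.
#'
#' @param ws An [inverse_weight_set()].
#' @param assignment Integer partition vector (0 = others).
#' @param r Optional precomputed correlation matrix of `ws`.
#' @param brute_cap Cluster size up to which polarity is solved exactly.
#' @param rng_seed Seed for the genetic polarity solver on large clusters.
#' @param cache Optional centroid cache (internal reuse).
#' @return Non-negative scalar.
#' @export
db_index <- function(ws, assignment, r = NULL, brute_cap = 15L,
                     rng_seed = 1L, cache = NULL) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  if (is.null(r)) r <- compute_correlation_matrix(ws)
  z <- as_partition_like(assignment, r)
  labs <- cluster_labels(z)
  if (length(labs) < 2L) {
    stop_icclust("Davies-Bouldin needs at least 2 clusters",
                 class = "icclust_no_cluster_error")
  }
  if (is.null(cache)) cache <- new_centroid_cache()
  cents <- lapply(labs, function(l) {
    cached_centroid(cache, ws, r, which(z == l), cap = brute_cap,
                    rng_seed = rng_seed)
  })
  d <- vapply(seq_along(labs), function(i) {
    mean(vapply(cents[[i]]$members, function(j) {
      centroid_similarity(cents[[i]], ws, j)
    }, 0))
  }, 0)
  k <- length(labs)
  cmap <- vapply(cents, function(cc) cc$map, numeric(nrow(ws$weights)))
  rmn <- abs(stats::cor(cmap))
  dbm <- vapply(seq_len(k), function(m) {
    max(vapply(setdiff(seq_len(k), m), function(n) {
      rmn[m, n] / (d[m] + d[n])
    }, 0))
  }, 0)
  mean(dbm)
}

#' Concordance of a partition with a reference eye-component set
#'
#' Given the set of components labelled "eye" by an external classifier,
#' scores how cleanly that set maps onto the clusters of the evaluated
#' partition: \deqn{RI_m = |C_{eye}| \sum_{C_i \cap C_{eye} \ne \emptyset}
#' \frac{1}{|C_i|},} where the sum runs over the partition's clusters that
#' intersect the eye set (the others pool is not a cluster and is skipped).
#' A single cluster exactly equal to the eye set scores 1; absorption into
#' a cluster twice its size scores 0.5. Note the sum is not clamped: if the
#' eye set fragments across many small clusters the index exceeds 1.
#'
#' @param assignment Integer partition vector (0 = others).
#' @param eye_ids Non-empty integer vector of reference eye component ids.
#' @return Non-negative scalar.
#' @export
rim_index <- function(assignment, eye_ids) {
  if (!length(eye_ids)) {
    stop_icclust("eye_ids must be non-empty",
                 class = "icclust_validation_error")
  }
  z <- if (is.double(assignment)) as.integer(round(assignment)) else assignment
  eye_ids <- as.integer(eye_ids)
  if (any(eye_ids < 1L) || any(eye_ids > length(z))) {
    stop_icclust("eye_ids out of range", class = "icclust_validation_error")
  }
  labs <- cluster_labels(z)
  hit <- labs[vapply(labs, function(l) any(z[eye_ids] == l), NA)]
  length(eye_ids) * sum(vapply(hit, function(l) 1 / sum(z == l), 0))
}

#' Full validity report for one partition
#'
#' Bundles all indices for a partition of an inverse-weight set: the
#' quality index `QI`, its local-density variant `QIhat`, the silhouette
#' average `Sh`, the inverted Davies-Bouldin `DB`, the eye-set concordance
#' `RIm` (only when `eye_ids` is supplied), cluster and outlier counts and
#' a per-cluster table. Indices that need at least two clusters (`Sh`,
#' `DB`) are reported as `NA` for degenerate partitions.
#'
#' @inheritParams db_index
#' @param fc Local-density factor for `QIhat`.
#' @param eye_ids Optional integer vector of reference eye components.
#' @param denominator Silhouette `a_i` divisor convention, see
#'   [silhouette_values()].
#' @return An object of class `cvi_report`.
#' @export
cvi_report <- function(ws, assignment, fc = 10L, eye_ids = NULL,
                       r = NULL, brute_cap = 15L, rng_seed = 1L,
                       denominator = "as_printed", cache = NULL) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  if (is.null(r)) r <- compute_correlation_matrix(ws)
  sim <- to_similarity(r)
  z <- as_partition_like(assignment, sim)
  labs <- cluster_labels(z)
  per <- data.frame(
    cluster = labs,
    size = vapply(labs, function(l) sum(z == l), 0L),
    QIc = vapply(labs, function(l) qic(sim, z, l), 0),
    QIc_hat = vapply(labs, function(l) qic_hat(sim, z, l, fc), 0)
  )
  nul <- function(expr) tryCatch(expr, icclust_no_cluster_error = function(e) NA_real_)
  structure(list(
    QI = nul(qi(sim, z)),
    QIhat = nul(qi_hat(sim, z, fc)),
    Sh = nul(sh_index(sim, z, denominator)),
    DB = nul(db_index(ws, z, r = r, brute_cap = brute_cap,
                      rng_seed = rng_seed, cache = cache)),
    RIm = if (is.null(eye_ids)) NA_real_ else rim_index(z, eye_ids),
    n_clusters = length(labs),
    n_others = n_others(z),
    per_cluster = per,
    fc = as.integer(fc)
  ), class = "cvi_report")
}

#' @export
print.cvi_report <- function(x, ...) {
  cat("Cluster validity report\n")
  cat(sprintf("  QI    = %.3f\n", x$QI))
  cat(sprintf("  QIhat = %.3f (fc = %d)\n", x$QIhat, x$fc))
  cat(sprintf("  Sh    = %s\n", format(round(x$Sh, 4))))
  cat(sprintf("  DB    = %s\n", format(round(x$DB, 4))))
  if (!is.na(x$RIm)) cat(sprintf("  RIm   = %.4f\n", x$RIm))
  cat(sprintf("  clusters = %d, others = %d\n", x$n_clusters, x$n_others))
  invisible(x)
}
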