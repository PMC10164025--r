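#' Symmetric normalized graph Laplacian of the similarity graph
#'
#' The similarity matrix is read as the adjacency matrix J of a weighted
#' undirected graph over components (self-loops kept: the diagonal of J is
#' 1 by construction). With D the degree matrix, the symmetric normalized
#' Laplacian is \eqn{L = I - D^{-1/2} J D^{-1/2}}. Its eigenvalues lie in
#' \eqn{[0, 2]}; the number of (near-)zero eigenvalues equals the number of
#' connected components of the graph.
#'
#' @param sim Similarity matrix from [to_similarity()].
#' @return Symmetric positive semi-definite matrix.
#' @export
normalized_laplacian <- function(sim) {
  check_square_symmetric(sim, "similarity matrix")
  d <- rowSums(sim)
  if (any(d <= 0)) {
    stop_icclust("all degrees must be positive",
                 class = "icclust_validation_error")
  }
  l <- diag(nrow(sim)) - sim / sqrt(outer(d, d))
  symmetrize(l)
}

#' Spectral embedding of components
#'
#' Computes the eigenvectors of the normalized Laplacian belonging to the k
#' smallest eigenvalues and arranges them as the columns of an n-by-k
#' matrix U. The rows \eqn{y_i} of U are the coordinates of the components
#' in the spectral space, where correlation-similar components fall close
#' together and ordinary k-means becomes effective.
#'
#' @param sim Similarity matrix.
#' @param k Number of eigenvectors, `2 <= k < n`.
#' @return Object of class `spectral_embedding`: list with `u` (n x k,
#'   columns ordered by ascending eigenvalue) and `eigenvalues` (all n,
#'   ascending).
#' @export
spectral_embedding <- function(sim, k) {
  check_square_symmetric(sim, "similarity matrix")
  n <- nrow(sim)
  if (k < 2L || k >= n) {
    stop_icclust("k must satisfy 2 <= k < n (n = ", n, ", k = ", k, ")",
                 class = "icclust_validation_error")
  }
  l <- normalized_laplacian(sim)
  e <- eigen(l, symmetric = TRUE)    # values in decreasing order
  vals <- rev(e$values)
  u <- e$vectors[, n:(n - k + 1L), drop = FALSE]
  structure(list(u = u, eigenvalues = vals, k = as.integer(k)),
            class = "spectral_embedding")
}

#' Eigengap diagnostic for the number of clusters
#'
#' Advisory inspection of the Laplacian spectrum: the count of near-zero
#' eigenvalues (disconnected blocks of the similarity graph) and the index
#' of the largest successive gap, which often marks a natural cluster
#' count. The pre-clustering k remains a user input; this only informs the
#' choice.
#'
#' @param eigenvalues Ascending vector of Laplacian eigenvalues.
#' @param zero_tol Threshold below which an eigenvalue counts as zero
#'   (default 1e-8).
#' @param window Optional integer range `c(lo, hi)` restricting where the
#'   largest gap is sought; default the whole spectrum.
#' @return List with `n_zero`, `k_suggested` (position of the largest gap:
#'   gap i is `lambda[i+1] - lambda[i]`), and `gaps`.
#' @export
eigengap_diagnostic <- function(eigenvalues, zero_tol = 1e-8, window = NULL) {
  ev <- as.numeric(eigenvalues)
  if (is.unsorted(ev, strictly = FALSE)) {
    stop_icclust("eigenvalues must be ascending",
                 class = "icclust_validation_error")
  }
  gaps <- diff(ev)
  idx <- seq_along(gaps)
  if (!is.null(window)) {
    idx <- idx[idx >= window[1] & idx <= window[2]]
    if (!length(idx)) {
      stop_icclust("empty eigengap window", class = "icclust_validation_error")
    }
  }
  list(n_zero = sum(ev < zero_tol),
       k_suggested = idx[which.max(gaps[idx])],
       gaps = gaps)
}

#' Spectral pre-clustering
#'
#' Embeds the components with [spectral_embedding()], normalizes each
#' embedding row to unit length, and partitions the rows with k-means
#' (no outlier mechanism at this stage: every component receives a
#' cluster). This partition seeds the clustering genetic algorithm, which
#' then adapts the cluster count and the outlier pool.
#'
#' k-means is run with `nstart` random restarts under a seed derived from
#' `rng_seed`, so the result is deterministic given the seed. If k-means
#' degenerates (an empty cluster), it is retried with fresh derived seeds
#' up to `retries` times.
#'
#' @param sim Similarity matrix.
#' @param k Number of pre-clusters.
#' @param rng_seed Integer seed.
#' @param nstart k-means restarts per attempt (default 10).
#' @param retries Maximum re-seeded attempts on degeneracy (default 10).
#' @return Integer assignment vector with exactly k clusters and an empty
#'   others pool.
#' @export
precluster <- function(sim, k, rng_seed = 1L, nstart = 10L, retries = 10L) {
  if (k == nrow(sim)) {
    # degenerate request: every component its own cluster
    return(seq_len(k))
  }
  emb <- spectral_embedding(sim, k)
  y <- emb$u
  nrm <- sqrt(rowSums(y^2))
  nrm[nrm < 1e-12] <- 1
  y <- y / nrm
  for (attempt in seq_len(retries)) {
    fit <- withr::with_seed(derive_seed(rng_seed, attempt - 1L), {
      tryCatch(
        stats::kmeans(y, centers = k, nstart = nstart, iter.max = 100L),
        error = function(e) NULL
      )
    })
    if (!is.null(fit) && length(unique(fit$cluster)) == k) {
      return(as_partition(as.integer(fit$cluster)))
    }
  }
  stop_icclust("k-means failed to produce ", k,
               " non-empty clusters after ", retries, " attempts",
               class = "icclust_kmeans_error")
}
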