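#' Cluster assignment vectors
#'
#' Throughout the package a partition of n components is an integer vector
#' of length n: label 0 marks the "others" pool (outliers, components
#' assigned to no cluster) and labels 1..k mark the clusters. These helpers
#' validate and normalize such vectors.
#'
#' `as_partition()` validates and compacts an assignment so that cluster
#' labels are the contiguous integers 1..k, in order of first appearance.
#' `fold_singletons()` additionally moves size-1 clusters into the others
#' pool: a single component is not a cluster, and the within-cluster term of
#' the quality indices is undefined for it.
#'
#' @param assignment Integer vector; 0 = others, positive integers = cluster
#'   labels.
#' @return An integer assignment vector with contiguous labels.
#' @examples
#' as_partition(c(5, 5, 0, 9, 9, 9))   # -> 1 1 0 2 2 2
#' fold_singletons(c(1, 1, 2, 3, 3))   # -> 1 1 0 2 2
#' @export
as_partition <- function(assignment) {
  z <- assignment
  if (is.double(z)) {
    if (any(z != round(z))) {
      stop_icclust("assignment labels must be integers",
                   class = "icclust_validation_error")
    }
    z <- as.integer(round(z))
  }
  if (!is.integer(z)) {
    stop_icclust("assignment must be an integer vector",
                 class = "icclust_validation_error")
  }
  if (anyNA(z) || any(z < 0L)) {
    stop_icclust("assignment labels must be >= 0 and non-missing",
                 class = "icclust_validation_error")
  }
  compact_labels(z)
}

# Relabel clusters to 1..k in order of first appearance; 0 is preserved.
compact_labels <- function(z) {
  labs <- unique(z[z > 0L])
  if (!length(labs)) return(z)
  map <- integer(max(labs))
  map[labs] <- seq_along(labs)
  out <- z
  out[z > 0L] <- map[z[z > 0L]]
  out
}

#' @rdname as_partition
#' @export
fold_singletons <- function(assignment) {
  z <- as_partition(assignment)
  sizes <- tabulate(z[z > 0L])
  single <- which(sizes == 1L)
  if (length(single)) z[z %in% single] <- 0L
  compact_labels(z)
}

#' @rdname as_partition
#' @export
cluster_labels <- function(assignment) {
  sort(unique(assignment[assignment > 0L]))
}

#' @rdname as_partition
#' @export
n_clusters <- function(assignment) length(cluster_labels(assignment))

#' @rdname as_partition
#' @export
n_others <- function(assignment) sum(assignment == 0L)

# List of member index vectors keyed by cluster label.
cluster_members <- function(z) {
  labs <- cluster_labels(z)
  stats::setNames(lapply(labs, function(l) which(z == l)), labs)
}
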