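#' Sign-corrected average scalp map of a cluster
#'
#' Each member column is RMS-normalized (divided by the root mean square of
#' its channel values), multiplied by its polarity sign, and the results are
#' averaged channel-wise. With signs from a polarity solver this yields a
#' centroid map that is not washed out by polarity inversions: a cluster
#' containing `v` and `-v` averages to `v` (up to global sign), not zero.
#'
#' @param ws An [inverse_weight_set()] (or plain weight matrix).
#' @param members Integer vector of component ids forming the cluster.
#' @param signs Numeric vector of -1/+1, one per member, typically from
#'   [solve_polarity_brute()] or [solve_polarity_ga()].
#' @return An object of class `ic_centroid`: list with `map` (channel
#'   vector), `members`, `signs`.
#' @export
compute_centroid <- function(ws, members, signs) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  members <- as.integer(members)
  if (!length(members)) {
    stop_icclust("centroid needs a non-empty member set",
                 class = "icclust_validation_error")
  }
  if (length(signs) != length(members)) {
    stop_icclust("signs length ", length(signs), " does not match ",
                 length(members), " members",
                 class = "icclust_validation_error")
  }
  if (!all(signs %in% c(-1, 1))) {
    stop_icclust("signs must be -1 or +1", class = "icclust_validation_error")
  }
  cols <- ws$weights[, members, drop = FALSE]
  rms <- sqrt(colMeans(cols^2))
  map <- as.numeric(cols %*% (signs / rms)) / length(members)
  structure(list(map = map, members = members, signs = as.numeric(signs)),
            class = "ic_centroid")
}

#' Similarity between a centroid and a component
#'
#' Absolute Pearson correlation between the centroid map and one
#' inverse-weight column, i.e. the same polarity-blind similarity used
#' between components.
#'
#' @param centroid An `ic_centroid` (or plain channel vector).
#' @param ws An [inverse_weight_set()].
#' @param component_id Column index of the component.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
centroid_similarity <- function(centroid, ws, component_id) {
  map <- if (inherits(centroid, "ic_centroid")) centroid$map else centroid
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  abs(stats::cor(map, ws$weights[, component_id]))
}

# Memoized centroid construction keyed by the (sorted) member set, so the
# clustering GA never re-solves polarity for an unchanged cluster.
new_centroid_cache <- function() new.env(parent = emptyenv())

cached_centroid <- function(cache, ws, r, members, cap = 15L, rng_seed = 1L) {
  members <- sort(as.integer(members))
  key <- paste(members, collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(members) == 1L) {
    cen <- compute_centroid(ws, members, 1)
    cen$cost <- 0
  } else {
    sol <- solve_polarity(r[members, members, drop = FALSE],
                          cap = cap, rng_seed = rng_seed)
    cen <- compute_centroid(ws, members, sol$signs)
    cen$cost <- sol$cost
  }
  cache[[key]] <- cen
  cen
}
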