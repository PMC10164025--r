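#' Specification of a synthetic inverse-weight set
#'
#' Describes a pooled multi-subject scalp-map matrix with planted cluster
#' structure. Defaults emulate the operating conditions of the method's
#' reference setting: 31 channels and 155 components (5 subjects of 31 ICs
#' pooled), six planted clusters with roughly 5% outliers, per-channel
#' Gaussian noise with `noise_sigma = 0.33` — which puts the expected
#' within-cluster absolute correlation near
#' \eqn{1/(1+\sigma^2) \approx 0.9} — and polarity flips with probability
#' 0.5, the maximally ambiguous case.
#'
#' @param n_channels Number of channels (rows).
#' @param cluster_sizes Integer vector of planted cluster sizes.
#' @param outlier_count Number of pure-noise columns.
#' @param noise_sigma Standard deviation of per-channel additive noise on
#'   cluster members (prototypes have unit channel variance).
#' @param flip_prob Probability each member's polarity is inverted.
#' @param max_proto_cor Maximum allowed absolute correlation between
#'   prototypes (default 0.3).
#' @param rng_seed Integer seed; generation is deterministic given it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 31L,
                           cluster_sizes = c(25L, 25L, 25L, 24L, 24L, 24L),
                           outlier_count = 8L, noise_sigma = 0.33,
                           flip_prob = 0.5, max_proto_cor = 0.3,
                           rng_seed = 1L) {
  stopifnot(n_channels >= 3, length(cluster_sizes) >= 1,
            all(cluster_sizes >= 1), outlier_count >= 0, noise_sigma >= 0,
            flip_prob >= 0, flip_prob <= 1, max_proto_cor > 0)
  structure(list(n_channels = as.integer(n_channels),
                 cluster_sizes = as.integer(cluster_sizes),
                 k_planted = length(cluster_sizes),
                 outlier_count = as.integer(outlier_count),
                 n_components = sum(cluster_sizes) + as.integer(outlier_count),
                 noise_sigma = noise_sigma, flip_prob = flip_prob,
                 max_proto_cor = max_proto_cor,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic inverse-weight set with planted clusters
#'
#' Draws `k_planted` prototype scalp maps (random Gaussian channel
#' vectors, orthogonalized by QR and re-noised so that all pairwise
#' absolute correlations stay below `max_proto_cor`, then rescaled to unit
#' channel variance). Each planted cluster member is its prototype, times
#' a random polarity flip, plus i.i.d. Gaussian channel noise; outlier
#' columns are pure Gaussian noise. The planted partition (outliers as
#' label 0) and the planted polarity flips are returned as ground truth
#' for recovery experiments.
#'
#' Components are attributed round-robin to five pseudo-subjects in the
#' metadata; the first planted cluster can optionally be tagged with the
#' `iclabel_class` "eye" (`label_eye_cluster`) so that the eye-concordance
#' index is exercised.
#'
#' @param spec A [synthetic_spec()].
#' @param label_eye_cluster Optional planted cluster label whose members
#'   are tagged `iclabel_class = "eye"` in the metadata.
#' @return List with `ws` (an [inverse_weight_set()]), `partition`
#'   (planted assignment, 0 = outlier), `signs` (planted flips, +1/-1,
#'   NA for outliers), `prototypes` (channels x k matrix), `spec`.
#' @export
generate_ic_set <- function(spec = synthetic_spec(),
                            label_eye_cluster = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$k_planted
  nc <- spec$n_channels
  if (k >= nc) {
    stop_icclust("cannot decorrelate ", k, " prototypes in ", nc,
                 " channels", class = "icclust_validation_error")
  }
  withr::with_seed(spec$rng_seed, {
    proto <- NULL
    for (attempt in 1:20) {
      g <- matrix(stats::rnorm(nc * k), nc, k)
      q <- qr.Q(qr(g))
      cand <- q + 0.15 * matrix(stats::rnorm(nc * k), nc, k)
      cand <- sweep(cand, 2, apply(cand, 2, stats::sd), "/")
      if (k == 1L || max(abs(stats::cor(cand)[upper.tri(diag(k))])) <=
            spec$max_proto_cor) {
        proto <- cand
        break
      }
    }
    if (is.null(proto)) {
      stop_icclust("failed to decorrelate prototypes below |r| = ",
                   spec$max_proto_cor,
                   class = "icclust_decorrelation_error")
    }
    n <- spec$n_components
    weights <- matrix(0, nc, n)
    partition <- integer(n)
    signs <- rep(NA_real_, n)
    col <- 0L
    for (c_i in seq_len(k)) {
      for (j in seq_len(spec$cluster_sizes[c_i])) {
        col <- col + 1L
        flip <- if (stats::runif(1) < spec$flip_prob) -1 else 1
        weights[, col] <- flip * proto[, c_i] +
          stats::rnorm(nc, 0, spec$noise_sigma)
        partition[col] <- c_i
        signs[col] <- flip
      }
    }
    if (spec$outlier_count > 0L) {
      for (j in seq_len(spec$outlier_count)) {
        col <- col + 1L
        weights[, col] <- stats::rnorm(nc)
      }
    }
    meta <- data.frame(
      component_id = seq_len(n),
      subject = sprintf("S%d", ((seq_len(n) - 1L) %% 5L) + 1L),
      ic_index = seq_len(n),
      iclabel_class = NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(label_eye_cluster)) {
      meta$iclabel_class[partition == label_eye_cluster] <- "eye"
    }
    list(ws = inverse_weight_set(weights, meta), partition = partition,
         signs = signs, prototypes = proto, spec = spec)
  })
}

#' A small correlation matrix illustrating polarity ambiguity
#'
#' Four components whose pairwise correlations make the naive
#' template-based polarity choice fail: taking component 1 as the template
#' yields signs `[1, 1, -1, -1]` (cost 2.4 under [polarity_cost()]),
#' flipping two components that are strongly positively correlated with
#' each other, while the global optimum `[1, 1, 1, -1]` has cost 0.2.
#'
#' @return A 4-by-4 symmetric correlation matrix.
#' @export
toy_correlation_matrix <- function() {
  matrix(c(1, 0.1, -0.1, -0.8,
           0.1, 1, 0.9, -0.5,
           -0.1, 0.9, 1, -0.3,
           -0.8, -0.5, -0.3, 1), 4, 4, byrow = TRUE)
}
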