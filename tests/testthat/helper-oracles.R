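# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code path with the package implementation.

oracle_pearson <- function(w) {
  n <- ncol(w)
  r <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- w[, i] - mean(w[, i])
      y <- w[, j] - mean(w[, j])
      r[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  r
}

# Eq-style polarity cost by explicit double loop over ordered pairs.
oracle_polarity_cost <- function(s, r) {
  m <- nrow(r)
  total <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      sgn <- if (r[i, j] < 0) -1 else 1
      total <- total + 0.5 * abs(s[i] * s[j] - sgn) * abs(r[i, j])
    }
  }
  total
}

# Exhaustive minimum of the polarity cost over all 2^m sign vectors.
oracle_polarity_min <- function(r) {
  m <- nrow(r)
  best <- Inf
  for (code in 0:(2^m - 1)) {
    s <- ifelse(bitwAnd(code, 2^(seq_len(m) - 1)) > 0, -1, 1)
    cost <- oracle_polarity_cost(s, r)
    if (cost < best) best <- cost
  }
  best
}

oracle_qic <- function(sim, z, m) {
  members <- which(z == m)
  others <- which(z != m)
  w <- 0
  for (i in members) for (j in members) if (i != j) w <- w + sim[i, j]
  w <- w / (length(members)^2 - length(members))
  b <- 0
  for (i in members) for (j in others) b <- b + sim[i, j]
  b <- b / (length(members) * length(others))
  100 * (w - b)
}

oracle_qi <- function(sim, z) {
  labs <- sort(unique(z[z > 0]))
  total <- 0
  for (l in labs) total <- total + sum(z == l) / length(z) * oracle_qic(sim, z, l)
  total
}

oracle_qic_hat <- function(sim, z, m, fc) {
  members <- which(z == m)
  others <- which(z != m)
  w <- 0
  for (i in members) for (j in members) if (i != j) w <- w + sim[i, j]
  w <- w / (length(members)^2 - length(members))
  vals <- c()
  for (i in members) for (j in others) vals <- c(vals, sim[i, j])
  vals <- sort(vals, decreasing = TRUE)
  p <- min(length(members) * fc, length(vals))
  100 * (w - mean(vals[seq_len(p)]))
}

oracle_qi_hat <- function(sim, z, fc) {
  labs <- sort(unique(z[z > 0]))
  total <- 0
  for (l in labs) {
    total <- total + sum(z == l) / length(z) * oracle_qic_hat(sim, z, l, fc)
  }
  total
}

oracle_silhouette <- function(sim, z, standard = FALSE) {
  labs <- sort(unique(z[z > 0]))
  idx <- which(z > 0)
  s <- numeric(0)
  for (i in idx) {
    own <- setdiff(which(z == z[i]), i)
    denom <- if (standard) length(own) else length(own) + 1
    a <- if (length(own)) sum(sim[i, own]) / denom else 0
    b <- -Inf
    for (l in labs[labs != z[i]]) {
      b <- max(b, mean(sim[i, which(z == l)]))
    }
    s <- c(s, (a - b) / max(a, b))
  }
  s
}

oracle_rim <- function(z, eye_ids) {
  labs <- sort(unique(z[z > 0]))
  total <- 0
  for (l in labs) {
    members <- which(z == l)
    if (length(intersect(members, eye_ids)) > 0) {
      total <- total + 1 / length(members)
    }
  }
  length(eye_ids) * total
}

# Random valid partition with n_clusters clusters and a few outliers.
random_partition <- function(n, k, n_out = 0) {
  repeat {
    z <- sample(seq_len(k), n, replace = TRUE)
    if (n_out > 0) z[sample(n, n_out)] <- 0
    sizes <- tabulate(z[z > 0], nbins = k)
    if (all(sizes >= 2)) return(as.integer(z))
  }
}

# Small random weight set whose columns have no special structure.
random_weights <- function(n_channels, n_components, seed) {
  withr::with_seed(seed, {
    matrix(rnorm(n_channels * n_components), n_channels, n_components)
  })
}

# Random symmetric correlation-like matrix with unit diagonal (entries are
# genuine correlations of random vectors, so it is a valid input).
random_corr <- function(m, seed, n_channels = 12) {
  icclust::compute_correlation_matrix(
    icclust::inverse_weight_set(random_weights(n_channels, m, seed)))
}

# Ideal block-diagonal similarity: b blocks, within 1, between 0.
block_similarity <- function(sizes) {
  n <- sum(sizes)
  sim <- matrix(0, n, n)
  start <- 1
  for (s in sizes) {
    idx <- start:(start + s - 1)
    sim[idx, idx] <- 1
    start <- start + s
  }
  sim
}
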