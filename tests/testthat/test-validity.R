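make_instance <- function(n, k, n_out, seed, n_channels = 10) {
  w <- random_weights(n_channels, n, seed)
  ws <- inverse_weight_set(w)
  sim <- to_similarity(compute_correlation_matrix(ws))
  z <- withr::with_seed(seed + 1, random_partition(n, k, n_out))
  list(ws = ws, sim = sim, z = z)
}

test_that("qic and qi match the double-loop oracle on random instances", {
  for (seed in 1:8) {
    inst <- make_instance(12, 3, n_out = seed %% 3, seed = seed)
    for (l in cluster_labels(inst$z)) {
      expect_equal(qic(inst$sim, inst$z, l), oracle_qic(inst$sim, inst$z, l),
                   tolerance = 1e-12)
    }
    expect_equal(qi(inst$sim, inst$z), oracle_qi(inst$sim, inst$z),
                 tolerance = 1e-12)
  }
})

test_that("qic hits its extremes on ideal similarity structure", {
  sim <- block_similarity(c(3, 3))
  z <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(qic(sim, z, 1), 100)
  expect_equal(qi(sim, z), 100)
  # within mean equal to between mean -> 0
  sim2 <- matrix(0.5, 6, 6)
  diag(sim2) <- 1
  expect_equal(qic(sim2, z, 1), 0)
})

test_that("qi weights clusters by size with outliers carrying no weight", {
  inst <- make_instance(10, 1, n_out = 0, seed = 3)
  z <- rep(0L, 10)
  z[c(4, 9)] <- 1L
  expect_equal(qi(inst$sim, z), 2 / 10 * qic(inst$sim, z, 1),
               tolerance = 1e-12)
})

test_that("singleton clusters score 0 with a warning; no clusters is an error", {
  inst <- make_instance(8, 2, n_out = 0, seed = 5)
  z <- inst$z
  z[z == 2] <- 0L
  z[which(z == 0L)[1]] <- 2L    # cluster 2 is now a singleton
  expect_warning(val <- qic(inst$sim, z, 2), "fewer than 2")
  expect_equal(val, 0)
  expect_error(qi(inst$sim, rep(0L, 8)), class = "icclust_no_cluster_error")
})

test_that("qic_hat matches the sort-and-average oracle and saturates to qic", {
  for (seed in 1:8) {
    inst <- make_instance(14, 3, n_out = 2, seed = seed + 20)
    for (l in cluster_labels(inst$z)) {
      expect_equal(qic_hat(inst$sim, inst$z, l, fc = 2),
                   oracle_qic_hat(inst$sim, inst$z, l, 2),
                   tolerance = 1e-12)
      # fc large enough to cover all between pairs: reduces to qic
      expect_equal(qic_hat(inst$sim, inst$z, l, fc = 50),
                   qic(inst$sim, inst$z, l), tolerance = 1e-12)
    }
    expect_equal(qi_hat(inst$sim, inst$z, fc = 2),
                 oracle_qi_hat(inst$sim, inst$z, 2), tolerance = 1e-12)
    expect_equal(qi_hat(inst$sim, inst$z, fc = 50), qi(inst$sim, inst$z),
                 tolerance = 1e-12)
  }
})

test_that("qic_hat equals qic when all between-similarities are equal", {
  sim <- matrix(0.4, 9, 9)
  diag(sim) <- 1
  sim[1:3, 1:3] <- 0.9
  diag(sim) <- 1
  z <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)
  expect_equal(qic_hat(sim, z, 1, fc = 1), qic(sim, z, 1), tolerance = 1e-12)
})

test_that("silhouettes match the oracle, stay in [-1, 1], and honor both denominators", {
  for (seed in 1:6) {
    inst <- make_instance(15, 3, n_out = 2, seed = seed + 40)
    s <- silhouette_values(inst$sim, inst$z)
    expect_equal(unname(s), oracle_silhouette(inst$sim, inst$z),
                 tolerance = 1e-12)
    expect_true(all(s >= -1 & s <= 1))
    expect_length(s, sum(inst$z > 0))
    s_std <- silhouette_values(inst$sim, inst$z, denominator = "standard")
    expect_equal(unname(s_std),
                 oracle_silhouette(inst$sim, inst$z, standard = TRUE),
                 tolerance = 1e-12)
    expect_equal(sh_index(inst$sim, inst$z), mean(s), tolerance = 1e-12)
  }
})

test_that("perfectly separated blocks give silhouette 1 even with the printed denominator", {
  sim <- block_similarity(c(4, 4))
  z <- rep(1:2, each = 4L)
  expect_equal(unname(silhouette_values(sim, z)), rep(1, 8))
  expect_equal(sh_index(sim, z), 1)
  expect_error(silhouette_values(sim, rep(1L, 8)),
               class = "icclust_no_cluster_error")
})

test_that("inverted Davies-Bouldin behaves on orthogonal and identical centroids", {
  # two orthogonal planted prototypes, no noise: centroid correlation ~ 0
  syn <- generate_ic_set(synthetic_spec(n_channels = 16,
    cluster_sizes = c(4, 4), outlier_count = 0, noise_sigma = 0,
    flip_prob = 0, max_proto_cor = 0.5, rng_seed = 2))
  db <- db_index(syn$ws, syn$partition)
  r <- compute_correlation_matrix(syn$ws)
  rmn <- abs(r[1, 5])    # inter-prototype similarity
  expect_equal(db, rmn / 2, tolerance = 1e-9)  # d_m = d_n = 1 exactly
  expect_error(db_index(syn$ws, rep(1L, 8)),
               class = "icclust_no_cluster_error")
})

test_that("Davies-Bouldin matches a direct computation with brute centroids", {
  for (seed in 1:4) {
    inst <- make_instance(12, 3, n_out = 1, seed = seed + 60, n_channels = 9)
    db <- db_index(inst$ws, inst$z)
    labs <- cluster_labels(inst$z)
    w <- inst$ws$weights
    r <- oracle_pearson(w)
    maps <- list()
    d <- numeric(length(labs))
    for (i in seq_along(labs)) {
      members <- which(inst$z == labs[i])
      sol <- solve_polarity_brute(r[members, members, drop = FALSE])
      map <- rep(0, nrow(w))
      for (jj in seq_along(members)) {
        col <- w[, members[jj]]
        map <- map + sol$signs[jj] * col / sqrt(mean(col^2))
      }
      maps[[i]] <- map / length(members)
      d[i] <- mean(sapply(members, function(j) {
        abs(oracle_pearson(cbind(maps[[i]], w[, j]))[1, 2])
      }))
    }
    dbm <- sapply(seq_along(labs), function(m) {
      max(sapply(setdiff(seq_along(labs), m), function(n) {
        abs(oracle_pearson(cbind(maps[[m]], maps[[n]]))[1, 2]) / (d[m] + d[n])
      }))
    })
    expect_equal(db, mean(dbm), tolerance = 1e-10)
  }
})

test_that("eye-concordance index matches set arithmetic", {
  z <- c(1L, 1L, 1L, 2L, 2L, 0L, 3L, 3L, 3L, 3L)
  expect_equal(rim_index(z, eye_ids = 1:3), 1)          # exact cluster match
  expect_equal(rim_index(z, eye_ids = c(7, 8)), 0.5)    # absorbed, half size
  for (seed in 1:5) {
    zr <- withr::with_seed(seed, random_partition(20, 4, 3))
    eyes <- withr::with_seed(seed + 1, sample(20, 5))
    expect_equal(rim_index(zr, eyes), oracle_rim(zr, eyes),
                 tolerance = 1e-12)
  }
  expect_error(rim_index(z, integer(0)), class = "icclust_validation_error")
})

test_that("indices are invariant to relabeling and to column sign flips", {
  inst <- make_instance(14, 3, n_out = 2, seed = 91)
  z <- inst$z
  zp <- z
  zp[z == 1L] <- 3L
  zp[z == 3L] <- 1L
  expect_equal(qi(inst$sim, z), qi(inst$sim, zp), tolerance = 1e-12)
  expect_equal(qi_hat(inst$sim, z, 10), qi_hat(inst$sim, zp, 10),
               tolerance = 1e-12)
  expect_equal(sh_index(inst$sim, z), sh_index(inst$sim, zp),
               tolerance = 1e-12)
  w2 <- inst$ws$weights
  w2[, c(2, 5, 9)] <- -w2[, c(2, 5, 9)]
  sim2 <- to_similarity(compute_correlation_matrix(inverse_weight_set(w2)))
  expect_equal(qi(sim2, z), qi(inst$sim, z), tolerance = 1e-10)
  expect_equal(db_index(inverse_weight_set(w2), z), db_index(inst$ws, z),
               tolerance = 1e-10)
})

test_that("cvi_report bundles all indices consistently", {
  syn <- generate_ic_set(synthetic_spec(n_channels = 16,
    cluster_sizes = c(5, 5, 5), outlier_count = 3, rng_seed = 8),
    label_eye_cluster = 1)
  eye_ids <- which(syn$ws$meta$iclabel_class == "eye")
  rep1 <- cvi_report(syn$ws, syn$partition, eye_ids = eye_ids)
  sim <- to_similarity(compute_correlation_matrix(syn$ws))
  expect_equal(rep1$QI, qi(sim, syn$partition), tolerance = 1e-12)
  expect_equal(rep1$QIhat, qi_hat(sim, syn$partition, 10), tolerance = 1e-12)
  expect_equal(rep1$Sh, sh_index(sim, syn$partition), tolerance = 1e-12)
  expect_equal(rep1$RIm, 1)
  expect_equal(rep1$n_clusters, 3L)
  expect_equal(rep1$n_others, 3L)
  expect_equal(nrow(rep1$per_cluster), 3L)
  # identical partitions yield identical reports (purely functional)
  rep2 <- cvi_report(syn$ws, syn$partition, eye_ids = eye_ids)
  expect_equal(rep1, rep2)
})
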