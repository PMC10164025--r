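small_synth <- function(seed = 4, sizes = c(6, 6, 6), n_out = 3) {
  generate_ic_set(synthetic_spec(n_channels = 16, cluster_sizes = sizes,
                                 outlier_count = n_out, rng_seed = seed))
}

test_that("cga_config validates its fields", {
  cfg <- cga_config()
  expect_equal(cfg$n_children, 20L)
  expect_equal(cfg$max_iter, 5000L)
  expect_equal(cfg$delta_iter, 250L)
  expect_equal(cfg$fc, 10L)
  expect_error(cga_config(alpha = 1.5))
  expect_error(cga_config(n_children = 0))
  expect_error(cga_config(delta_iter = 0))
})

test_that("split moves a member to others and folds emptied pairs", {
  syn <- small_synth()
  ws <- syn$ws
  z <- syn$partition
  z2 <- mutate_partition(z, component_id = 1, ws, u = 0.2, beta = 0.5)
  expect_equal(z2[1], 0L)
  expect_equal(sum(z2 == z[1] & seq_along(z2) != 1), 5)
  # splitting one member of a 2-cluster dissolves it entirely
  z3 <- z
  z3[z3 == 2L] <- 0L
  z3[c(7, 8)] <- 2L
  z4 <- mutate_partition(z3, component_id = 7, ws, u = 0.2)
  expect_equal(n_others(z4), n_others(z3) + 2)
})

test_that("merge pairs an outlier with its most similar fellow outlier", {
  syn <- small_synth()
  z <- syn$partition
  out <- which(z == 0L)
  sim <- to_similarity(compute_correlation_matrix(syn$ws))
  z2 <- mutate_partition(z, component_id = out[1], syn$ws, u = 0.2,
                         alpha = 0.5, sim = sim)
  new_lab <- z2[out[1]]
  expect_gt(new_lab, 0L)
  partner <- setdiff(which(z2 == new_lab), out[1])
  expect_equal(length(partner), 1L)
  expect_equal(partner,
               out[-1][which.max(sim[out[1], out[-1]])])
  expect_equal(n_others(z2), length(out) - 2)
})

test_that("merge falls back to agglomerative when no other outlier exists", {
  syn <- small_synth(n_out = 1)
  z <- syn$partition
  out <- which(z == 0L)
  z2 <- mutate_partition(z, component_id = out, syn$ws, u = 0.1)
  expect_gt(z2[out], 0L)                  # joined an existing cluster
  expect_equal(n_clusters(z2), n_clusters(z))
})

test_that("agglomerative joins the cluster with the most similar centroid", {
  syn <- small_synth(n_out = 2)
  # plant an extra copy of cluster 1's prototype as an outlier
  w <- cbind(syn$ws$weights, syn$prototypes[, 1] + rnorm(16, 0, 0.05))
  ws <- inverse_weight_set(w)
  z <- c(syn$partition, 0L)
  n <- length(z)
  z2 <- mutate_partition(z, component_id = n, ws, u = 0.9, alpha = 0.5)
  expect_equal(z2[n], 1L)
})

test_that("move is a fixed point when the own centroid is closest", {
  syn <- small_synth()
  z <- syn$partition
  # a clean member of a tight planted cluster stays put
  z2 <- mutate_partition(z, component_id = 2, syn$ws, u = 0.9, beta = 0.5)
  expect_equal(z2, as_partition(z))
})

test_that("every mutation preserves the partition invariant", {
  syn <- small_synth()
  z <- as_partition(syn$partition)
  sim <- to_similarity(compute_correlation_matrix(syn$ws))
  withr::with_seed(99, {
    for (rep in 1:40) {
      comp <- sample(length(z), 1)
      z <- mutate_partition(z, comp, syn$ws, u = runif(1), sim = sim)
      expect_length(z, length(syn$partition))
      expect_true(all(z >= 0L))
      sizes <- tabulate(z[z > 0L])
      expect_true(all(sizes[sizes > 0] >= 2))   # no singleton survives
      labs <- cluster_labels(z)
      expect_equal(labs, seq_along(labs))       # compact labels
    }
  })
})

test_that("child fitness from the incremental path equals full recomputation", {
  syn <- small_synth(seed = 6)
  ws <- syn$ws
  r <- compute_correlation_matrix(ws)
  sim <- to_similarity(r)
  z <- fold_singletons(precluster(sim, 3, rng_seed = 2))
  fit <- run_cga(z, ws, cga_config(max_iter = 30, delta_iter = 30,
                                   rng_seed = 5), sim = sim, r = r)
  # every recorded fitness must equal qi_hat recomputed from scratch on a
  # partition reachable by mutations; check at least the final state
  expect_equal(fit$fitness, qi_hat(sim, fit$partition, fc = 10),
               tolerance = 1e-10)
  expect_equal(fit$history$fitness[1], qi_hat(sim, fold_singletons(z), 10),
               tolerance = 1e-10)
})

test_that("elitism makes the fitness history non-decreasing", {
  for (seed in 1:3) {
    syn <- small_synth(seed = seed)
    sim <- to_similarity(compute_correlation_matrix(syn$ws))
    pre <- precluster(sim, 2 + seed, rng_seed = seed)
    fit <- run_cga(pre, syn$ws,
                   cga_config(max_iter = 120, delta_iter = 60,
                              rng_seed = seed), sim = sim)
    expect_true(all(diff(fit$history$fitness) >= 0))
  }
})

test_that("max_iter = 0 returns the seed partition unchanged", {
  syn <- small_synth(seed = 9)
  pre <- precluster(to_similarity(compute_correlation_matrix(syn$ws)), 3,
                    rng_seed = 1)
  fit <- run_cga(pre, syn$ws, cga_config(max_iter = 0, rng_seed = 1))
  expect_equal(fit$partition, fold_singletons(pre))
  expect_equal(fit$iterations, 0L)
  expect_s3_class(fit$report, "cvi_report")
})

test_that("an already perfect partition of an ideal set is never degraded", {
  syn <- generate_ic_set(synthetic_spec(n_channels = 16,
    cluster_sizes = c(5, 5), outlier_count = 0, noise_sigma = 0,
    flip_prob = 0.5, rng_seed = 14))
  sim <- to_similarity(compute_correlation_matrix(syn$ws))
  fit <- run_cga(syn$partition, syn$ws,
                 cga_config(max_iter = 80, delta_iter = 80, rng_seed = 3),
                 sim = sim)
  expect_equal(fit$partition, as_partition(syn$partition))
})

test_that("identical seeds give identical runs; different seeds may differ", {
  syn <- small_synth(seed = 10)
  cfg <- cga_config(max_iter = 60, delta_iter = 30, rng_seed = 42)
  a <- cluster_ics(syn$ws, k = 3, config = cfg)
  b <- cluster_ics(syn$ws, k = 3, config = cfg)
  expect_identical(a$partition, b$partition)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$report$QIhat, b$report$QIhat)
  expect_identical(a$history, b$history)
})

test_that("the end-to-end pipeline recovers planted structure and emits artifacts", {
  syn <- generate_ic_set(synthetic_spec(n_channels = 20,
    cluster_sizes = c(8, 8, 8), outlier_count = 0, noise_sigma = 0.2,
    rng_seed = 17))
  res <- cluster_ics(syn$ws, k = 3,
                     config = cga_config(max_iter = 100, delta_iter = 50,
                                         rng_seed = 1))
  expect_equal(mclust::adjustedRandIndex(res$partition, syn$partition), 1)
  expect_equal(ncol(res$centroids), 3)
  expect_equal(nrow(res$assignment), 24)
  expect_true(all(res$assignment$sign[res$partition > 0] %in% c(-1, 1)))
  expect_true(all(c("cluster", "component_id", "similarity") %in%
                    names(res$edges)))
  # every cluster is connected at least to all of its own members
  for (l in cluster_labels(res$partition)) {
    own <- which(res$partition == l)
    expect_true(all(own %in% res$edges$component_id[res$edges$cluster == l]))
  }
})

test_that("a 4-component set realizing the demo correlations runs end-to-end", {
  # build 4 maps whose correlation signs mirror the demo matrix pattern
  base <- withr::with_seed(8, rnorm(12))
  noise <- function(s) withr::with_seed(s, rnorm(12, 0, 0.6))
  w <- cbind(base + noise(1), base + noise(2), base + noise(3),
             -base + noise(4))
  ws <- inverse_weight_set(w)
  res <- cluster_ics(ws, k = 2,
                     config = cga_config(max_iter = 10, delta_iter = 5,
                                         rng_seed = 1))
  expect_s3_class(res, "icclust_result")
  expect_length(res$partition, 4)
})
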