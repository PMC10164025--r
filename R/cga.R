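#' Configuration for the clustering genetic algorithm
#'
#' Defaults follow the reference operating point of the method: 20
#' children per generation, equal-probability mutation branches
#' (`alpha = beta = 0.5`), up to 5000 iterations with an early stop after
#' 250 iterations without strict improvement, and local-density factor
#' `fc = 10`.
#'
#' @param n_children Children generated per iteration (Nc).
#' @param alpha For an outlier component, probability of the *merge*
#'   mutation (else *agglomerative*).
#' @param beta For a clustered component, probability of the *split*
#'   mutation (else *move*).
#' @param max_iter Maximum iterations; 0 returns the seed partition
#'   unchanged.
#' @param delta_iter Stop after this many iterations without strict fitness
#'   improvement.
#' @param fc Local-density regularization factor of the fitness
#'   ([qi_hat()]).
#' @param rng_seed Root seed; every stochastic step derives from it.
#' @param brute_polarity_cap Cluster size up to which centroid polarity is
#'   solved exactly; larger clusters use the genetic polarity solver.
#' @return Object of class `cga_config`.
#' @export
cga_config <- function(n_children = 20L, alpha = 0.5, beta = 0.5,
                       max_iter = 5000L, delta_iter = 250L, fc = 10L,
                       rng_seed = 1L, brute_polarity_cap = 15L) {
  stopifnot(n_children >= 1, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            max_iter >= 0, delta_iter >= 1, fc >= 1, brute_polarity_cap >= 1)
  structure(list(n_children = as.integer(n_children), alpha = alpha,
                 beta = beta, max_iter = as.integer(max_iter),
                 delta_iter = as.integer(delta_iter), fc = as.integer(fc),
                 rng_seed = as.integer(rng_seed),
                 brute_polarity_cap = as.integer(brute_polarity_cap)),
            class = "cga_config")
}

# Fold clusters reduced to one member into the others pool without
# relabelling (internal GA representation keeps labels stable).
fold_singletons_raw <- function(z) {
  labs <- unique(z[z > 0L])
  for (l in labs) if (sum(z == l) == 1L) z[z == l] <- 0L
  z
}

# qic_hat on raw member indices, assuming unit diagonal similarity.
qhat_members <- function(sim, members, fc) {
  m <- length(members)
  dsum <- sum(sim[cbind(members, members)])
  w <- (sum(sim[members, members]) - dsum) / (m^2 - m)
  v <- as.numeric(sim[members, -members, drop = FALSE])
  if (!length(v)) return(100 * w)
  p <- min(m * fc, length(v))
  b <- mean(sort(v, decreasing = TRUE)[seq_len(p)])
  100 * (w - b)
}

# Per-label qic_hat table for a whole assignment.
qhat_table <- function(sim, z, fc) {
  labs <- unique(z[z > 0L])
  stats::setNames(vapply(labs, function(l) qhat_members(sim, which(z == l), fc), 0),
                  as.character(labs))
}

fitness_from_table <- function(z, qh) {
  if (!length(qh)) return(0)
  labs <- as.integer(names(qh))
  sizes <- vapply(labs, function(l) sum(z == l), 0L)
  sum(sizes * qh) / length(z)
}

# One mutation applied to component `comp` of assignment `z` (raw labels,
# no compaction; singletons folded). `u` is the branch draw in [0, 1).
mutate_once <- function(z, comp, ws, sim, r, cache, alpha, beta, u,
                        cap = 15L, rng_seed = 1L) {
  lab <- z[comp]
  labs <- sort(unique(z[z > 0L]))
  closest_cluster <- function() {
    if (!length(labs)) return(NA_integer_)
    cs <- vapply(labs, function(l) {
      cen <- cached_centroid(cache, ws, r, which(z == l), cap = cap,
                             rng_seed = rng_seed)
      if (l == lab) {
        # own cluster: score against the centroid with the component
        # removed, otherwise its own contribution biases the comparison
        m <- length(cen$members)
        if (m < 2L) return(-Inf)
        i <- match(comp, cen$members)
        x <- ws$weights[, comp]
        loo <- (m * cen$map - cen$signs[i] * x / sqrt(mean(x^2))) / (m - 1L)
        abs(stats::cor(loo, x))
      } else {
        abs(stats::cor(cen$map, ws$weights[, comp]))
      }
    }, 0)
    labs[which.max(cs)]    # ties: lowest label
  }
  if (lab == 0L) {
    other_out <- setdiff(which(z == 0L), comp)
    if (u < alpha && length(other_out)) {
      # merge: pair with the most similar fellow outlier into a new cluster
      o <- other_out[which.max(sim[comp, other_out])]
      new_lab <- max(z, 0L) + 1L
      z[c(comp, o)] <- new_lab
    } else {
      # agglomerative: join the cluster with the closest centroid
      target <- closest_cluster()
      if (!is.na(target)) z[comp] <- target
    }
  } else {
    if (u < beta) {
      z[comp] <- 0L                      # split: demote to outlier
    } else {
      target <- closest_cluster()        # move (own cluster may win: no-op)
      if (!is.na(target) && target != lab) z[comp] <- target
    }
  }
  fold_singletons_raw(z)
}

#' Apply one clustering mutation to a partition
#'
#' One step of the clustering GA's variation scheme, applied to a chosen
#' component. An outlier component is either *merged* with its most similar
#' fellow outlier into a new two-member cluster (probability `alpha`;
#' falls back to agglomerative when no other outlier exists) or joined
#' *agglomeratively* to the cluster whose centroid it correlates with most.
#' A clustered component is either *split* off into the others pool
#' (probability `beta`) or *moved* to the cluster with the closest
#' centroid (which may be its own, leaving the partition unchanged).
#' Clusters reduced to a single member are folded into the others pool and
#' labels are compacted.
#'
#' @param assignment Integer partition vector (0 = others).
#' @param component_id Component to mutate.
#' @param ws An [inverse_weight_set()].
#' @param alpha,beta Branch probabilities, see above.
#' @param u Optional uniform draw in \eqn{[0,1)} deciding the branch;
#'   drawn from the session RNG when `NULL`.
#' @param sim,r Optional precomputed similarity/correlation matrices.
#' @param brute_polarity_cap,rng_seed Centroid polarity solver controls.
#' @return A new integer assignment vector.
#' @export
mutate_partition <- function(assignment, component_id, ws, alpha = 0.5,
                             beta = 0.5, u = NULL, sim = NULL, r = NULL,
                             brute_polarity_cap = 15L, rng_seed = 1L) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  if (is.null(r)) r <- compute_correlation_matrix(ws)
  if (is.null(sim)) sim <- to_similarity(r)
  z <- as_partition(assignment)
  if (component_id < 1L || component_id > length(z)) {
    stop_icclust("component_id out of range",
                 class = "icclust_validation_error")
  }
  if (is.null(u)) u <- stats::runif(1)
  cache <- new_centroid_cache()
  compact_labels(mutate_once(z, as.integer(component_id), ws, sim, r, cache,
                             alpha, beta, u, cap = brute_polarity_cap,
                             rng_seed = rng_seed))
}

#' Refine a partition with the elitist clustering genetic algorithm
#'
#' Starting from a seed partition (normally the spectral pre-clustering),
#' each iteration generates `n_children` candidate partitions, each
#' obtained by applying one mutation ([mutate_partition()]) to one
#' uniformly drawn component of the current seed. Candidates are scored by
#' the local-density quality index [qi_hat()]; the best of seed and
#' children becomes the next seed, so the fitness history is non-decreasing
#' (elitism). The run stops after `max_iter` iterations or `delta_iter`
#' iterations without strict improvement. Because mutations create and
#' delete clusters and populate the others pool, the cluster count adapts
#' automatically.
#'
#' Scoring is incremental: a child differs from the seed in at most one
#' component's assignment, which only changes the quality terms of the
#' clusters it left or joined; all other per-cluster terms are reused.
#' Centroids used by the mutation operators are memoized by member set.
#'
#' @param pre Seed partition (integer vector, 0 = others). Singleton
#'   clusters are folded before scoring.
#' @param ws An [inverse_weight_set()].
#' @param config A [cga_config()].
#' @param sim,r Optional precomputed matrices.
#' @param eye_ids Optional reference eye components for the final report's
#'   RIm.
#' @return Object of class `cga_fit`: list with `partition` (compacted),
#'   `report` (a [cvi_report()]), `history` (data frame of iteration and
#'   fitness), `fitness`, `iterations`, `config`.
#' @export
run_cga <- function(pre, ws, config = cga_config(), sim = NULL, r = NULL,
                    eye_ids = NULL) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  if (!inherits(config, "cga_config")) {
    stop_icclust("config must be a cga_config",
                 class = "icclust_validation_error")
  }
  if (is.null(r)) r <- compute_correlation_matrix(ws)
  if (is.null(sim)) sim <- to_similarity(r)
  n <- ncol(ws$weights)
  cache <- new_centroid_cache()
  z <- fold_singletons_raw(as_partition(pre))
  qh <- qhat_table(sim, z, config$fc)
  fitness <- fitness_from_table(z, qh)
  history <- list(data.frame(iteration = 0L, fitness = fitness))
  iterations <- 0L
  if (config$max_iter > 0L) {
    withr::with_seed(config$rng_seed, {
      stagnant <- 0L
      for (iter in seq_len(config$max_iter)) {
        if (stagnant >= config$delta_iter) break
        iterations <- iter
        best_fit <- -Inf
        best_z <- NULL
        best_qh <- NULL
        comps <- sample.int(n, config$n_children, replace = TRUE)
        us <- stats::runif(config$n_children)
        for (j in seq_len(config$n_children)) {
          z2 <- mutate_once(z, comps[j], ws, sim, r, cache,
                            config$alpha, config$beta, us[j],
                            cap = config$brute_polarity_cap,
                            rng_seed = config$rng_seed)
          changed <- which(z2 != z)
          if (!length(changed)) {
            fit2 <- fitness
            qh2 <- qh
          } else {
            affected <- setdiff(unique(c(z[changed], z2[changed])), 0L)
            qh2 <- qh
            for (l in affected) {
              key <- as.character(l)
              if (any(z2 == l)) {
                qh2[[key]] <- qhat_members(sim, which(z2 == l), config$fc)
              } else {
                qh2 <- qh2[names(qh2) != key]
              }
            }
            fit2 <- fitness_from_table(z2, qh2)
          }
          if (fit2 > best_fit) {
            best_fit <- fit2
            best_z <- z2
            best_qh <- qh2
          }
        }
        if (best_fit > fitness) {
          z <- best_z
          qh <- best_qh
          fitness <- best_fit
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        history[[length(history) + 1L]] <-
          data.frame(iteration = iter, fitness = fitness)
      }
    })
  }
  zc <- compact_labels(z)
  report <- cvi_report(ws, zc, fc = config$fc, eye_ids = eye_ids, r = r,
                       brute_cap = config$brute_polarity_cap,
                       rng_seed = config$rng_seed)
  structure(list(partition = zc, report = report,
                 history = do.call(rbind, history), fitness = fitness,
                 iterations = iterations, config = config),
            class = "cga_fit")
}

#' @export
print.cga_fit <- function(x, ...) {
  cat("Clustering GA fit:", x$iterations, "iterations, fitness (QIhat) =",
      round(x$fitness, 3), "\n")
  cat("Final partition:", n_clusters(x$partition), "clusters,",
      n_others(x$partition), "others\n")
  invisible(x)
}

#' End-to-end clustering of an inverse-weight set
#'
#' Runs the full pipeline: absolute-correlation similarity, spectral
#' pre-clustering with `k` groups, refinement by the elitist clustering GA,
#' and the validity report. Also assembles the downstream artifacts: the
#' per-component assignment table (with the polarity sign each clustered
#' component receives in its centroid), the centroid maps, and the
#' centroid-connection edge list, which links centroid m to every component
#' whose similarity to the centroid is at least the weakest of m's own
#' members — a compact picture of cluster separation.
#'
#' @param ws An [inverse_weight_set()] (or plain weight matrix).
#' @param k Number of spectral pre-clusters (the GA adapts the final
#'   count).
#' @param config A [cga_config()].
#' @param eye_ids Optional reference eye components for RIm; when `NULL`
#'   and the metadata has `iclabel_class == "eye"` entries, those are used.
#' @return Object of class `icclust_result` with elements `partition`,
#'   `report`, `assignment` (data frame: component_id, subject, cluster,
#'   sign), `centroids` (channels x clusters matrix), `edges` (data frame:
#'   cluster, component_id, similarity), `precluster`, `history`, `config`,
#'   `k`.
#' @examples
#' syn <- generate_ic_set(synthetic_spec(n_channels = 16,
#'   cluster_sizes = c(6, 6, 6), outlier_count = 2, rng_seed = 3))
#' res <- cluster_ics(syn$ws, k = 3,
#'                    config = cga_config(max_iter = 50, delta_iter = 25))
#' res$report$QI
#' @export
cluster_ics <- function(ws, k, config = cga_config(), eye_ids = NULL) {
  if (!inherits(ws, "inverse_weight_set")) ws <- inverse_weight_set(ws)
  r <- compute_correlation_matrix(ws)
  sim <- to_similarity(r)
  if (is.null(eye_ids)) {
    eyes <- which(!is.na(ws$meta$iclabel_class) &
                    ws$meta$iclabel_class == "eye")
    if (length(eyes)) eye_ids <- eyes
  }
  pre <- precluster(sim, k, rng_seed = config$rng_seed)
  fit <- run_cga(pre, ws, config = config, sim = sim, r = r,
                 eye_ids = eye_ids)
  z <- fit$partition
  labs <- cluster_labels(z)
  cache <- new_centroid_cache()
  cents <- lapply(labs, function(l) {
    cached_centroid(cache, ws, r, which(z == l),
                    cap = config$brute_polarity_cap,
                    rng_seed = config$rng_seed)
  })
  signs <- rep(NA_real_, length(z))
  for (cc in cents) signs[cc$members] <- cc$signs
  assignment <- data.frame(component_id = ws$meta$component_id,
                           subject = ws$meta$subject,
                           cluster = z, sign = signs,
                           stringsAsFactors = FALSE)
  centroids <- NULL
  edges <- NULL
  if (length(cents)) {
    centroids <- vapply(cents, function(cc) cc$map,
                        numeric(nrow(ws$weights)))
    colnames(centroids) <- labs
    simc <- abs(stats::cor(centroids, ws$weights))   # k x n
    edge_rows <- lapply(seq_along(labs), function(i) {
      thr <- min(simc[i, which(z == labs[i])])
      hits <- which(simc[i, ] >= thr)
      data.frame(cluster = labs[i], component_id = hits,
                 similarity = as.numeric(simc[i, hits]))
    })
    edges <- do.call(rbind, edge_rows)
  }
  structure(list(partition = z, report = fit$report,
                 assignment = assignment, centroids = centroids,
                 edges = edges, precluster = pre, history = fit$history,
                 fitness = fit$fitness, config = config, k = as.integer(k)),
            class = "icclust_result")
}

#' @export
print.icclust_result <- function(x, ...) {
  cat("IC topography clustering (k_pre =", x$k, ")\n")
  print(x$report)
  invisible(x)
}
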