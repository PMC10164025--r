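#' Polarity-inversion cost of a sign vector
#'
#' ICA scalp maps carry an arbitrary polarity, so before averaging a
#' cluster into a centroid each member must be flipped to a common
#' orientation. A candidate orientation is a sign vector
#' \eqn{s \in \{-1, +1\}^m}. Its cost is the total absolute correlation
#' carried by pairs whose imposed sign relation \eqn{s_i s_j} disagrees with
#' the observed sign of the correlation:
#' \deqn{\mathrm{cost}(s) = \sum_{i,j} \tfrac12\,|s_i s_j - \mathrm{sgn}(r_{ij})|\,|r_{ij}|,}
#' summed over all ordered pairs (the diagonal contributes zero). The cost
#' is invariant under a global flip (`cost(s) == cost(-s)`) and is zero
#' exactly when `outer(s, s)` reproduces the sign pattern of `r` wherever
#' `r` is nonzero.
#'
#' An equivalent closed form, used internally for speed, is
#' \eqn{(\sum_{ij} |r_{ij}| - s^\top r\, s)/2}: minimizing the cost is the
#' same as maximizing the quadratic form \eqn{s^\top r s}.
#'
#' @param s Sign vector of -1/+1 values, one per cluster member.
#' @param r_sub Symmetric correlation matrix restricted to the cluster.
#' @return Non-negative scalar cost.
#' @seealso [solve_polarity_brute()], [solve_polarity_ga()]
#' @examples
#' r <- toy_correlation_matrix()
#' polarity_cost(c(1, 1, -1, -1), r)  # template-based choice: 2.4
#' polarity_cost(c(1, 1, 1, -1), r)   # global optimum: 0.2
#' @export
polarity_cost <- function(s, r_sub) {
  check_square_symmetric(r_sub, "r_sub")
  if (length(s) != nrow(r_sub)) {
    stop_icclust("sign vector length ", length(s), " does not match matrix",
                 " dimension ", nrow(r_sub),
                 class = "icclust_validation_error")
  }
  if (!all(s %in% c(-1, 1))) {
    stop_icclust("sign vector entries must be -1 or +1",
                 class = "icclust_validation_error")
  }
  sgn <- sign_matrix(r_sub)
  sum(0.5 * abs(outer(s, s) - sgn) * abs(r_sub))
}

# Sign pattern of a correlation matrix; sign(0) is defined as +1 (a zero
# correlation carries zero weight in the cost, so the choice is immaterial).
sign_matrix <- function(r) {
  s <- matrix(1, nrow(r), ncol(r))
  s[r < 0] <- -1
  s
}

# Vectorized cost for a population of sign vectors (columns of p) via the
# quadratic identity; equals polarity_cost column by column.
polarity_cost_population <- function(p, r) {
  (sum(abs(r)) - colSums(p * (r %*% p))) / 2
}

#' Exact polarity solver by exhaustive enumeration
#'
#' Enumerates the \eqn{2^{m-1}} canonical sign vectors (first entry fixed to
#' +1; `s` and `-s` are equivalent) and returns a global minimizer of
#' [polarity_cost()]. Intended for small clusters; refuses above `cap`
#' members, where [solve_polarity_ga()] should be used instead.
#'
#' @param r_sub Symmetric correlation matrix restricted to the cluster.
#' @param cap Maximum cluster size accepted (default 15).
#' @return A list with `signs` (the minimizer, first entry +1) and `cost`.
#' @examples
#' solve_polarity_brute(toy_correlation_matrix())
#' @export
solve_polarity_brute <- function(r_sub, cap = 15L) {
  check_square_symmetric(r_sub, "r_sub")
  m <- nrow(r_sub)
  if (m > cap) {
    stop_icclust("cluster size ", m, " exceeds the brute-force cap (", cap,
                 "); use solve_polarity_ga()",
                 class = "icclust_brute_cap_error")
  }
  if (m == 1L) return(list(signs = 1, cost = 0))
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m - 1L),
                                KEEP.OUT.ATTRS = FALSE))
  p <- rbind(1, t(grid))          # m x 2^(m-1), first gene fixed +1
  costs <- polarity_cost_population(p, r_sub)
  best <- which.min(costs)        # ties: lowest index, deterministic
  list(signs = as.numeric(p[, best]), cost = costs[best])
}

#' Genetic polarity solver for large clusters
#'
#' Minimizes [polarity_cost()] with a small elitist genetic algorithm over
#' binary sign strings (first gene fixed to +1). The population is seeded
#' with the all-ones vector, a greedy sign propagation over the maximum-|r|
#' spanning tree of the cluster (breadth-first, each component taking its
#' parent's sign times the sign of the connecting correlation), and random
#' vectors; children are produced by tournament selection, uniform
#' crossover and per-gene flip mutation, and the incumbent is polished by a
#' greedy single-flip descent (flip the entry with the largest cost
#' reduction until 1-opt). The best-so-far solution is always retained, so
#' the returned cost never exceeds the cost of the all-ones vector.
#'
#' @param r_sub Symmetric correlation matrix restricted to the cluster
#'   (size at least 2).
#' @param rng_seed Integer seed; the solver is deterministic given the seed.
#' @param pop_size Population size (default 20).
#' @param max_gen Maximum generations (default 200).
#' @param stagnation Stop after this many generations without improvement
#'   (default 50).
#' @param crossover_rate Probability a child is produced by uniform
#'   crossover rather than cloning (default 0.8).
#' @param mutation_rate Per-gene flip probability; default `1/m`.
#' @return A list with `signs` (first entry +1) and `cost`.
#' @export
solve_polarity_ga <- function(r_sub, rng_seed = 1L, pop_size = 20L,
                              max_gen = 200L, stagnation = 50L,
                              crossover_rate = 0.8, mutation_rate = NULL) {
  check_square_symmetric(r_sub, "r_sub")
  m <- nrow(r_sub)
  if (m < 2L) {
    stop_icclust("polarity GA needs a cluster of size >= 2",
                 class = "icclust_validation_error")
  }
  if (is.null(mutation_rate)) mutation_rate <- 1 / m
  withr::with_seed(rng_seed, {
    pop <- matrix(1, m, pop_size)
    pop[, 2] <- spanning_tree_signs(r_sub)
    if (pop_size > 2L) {
      rnd <- matrix(sample(c(-1, 1), m * (pop_size - 2L), replace = TRUE),
                    m, pop_size - 2L)
      pop[, 3:pop_size] <- rnd
    }
    pop[1, ] <- 1
    pop[, 1] <- single_flip_descent(pop[, 1], r_sub)
    pop[, 2] <- single_flip_descent(pop[, 2], r_sub)
    costs <- polarity_cost_population(pop, r_sub)
    best_i <- which.min(costs)
    best <- pop[, best_i]
    best_cost <- costs[best_i]
    stagnant <- 0L
    for (gen in seq_len(max_gen)) {
      if (stagnant >= stagnation) break
      newpop <- matrix(0, m, pop_size)
      newpop[, 1] <- best                 # elitism
      for (j in 2:pop_size) {
        a <- pop[, tournament_pick(costs)]
        if (stats::runif(1) < crossover_rate) {
          b <- pop[, tournament_pick(costs)]
          mask <- stats::runif(m) < 0.5
          child <- ifelse(mask, a, b)
        } else {
          child <- a
        }
        flip <- stats::runif(m) < mutation_rate
        child[flip] <- -child[flip]
        child[1] <- 1
        newpop[, j] <- child
      }
      pop <- newpop
      costs <- polarity_cost_population(pop, r_sub)
      gi <- which.min(costs)
      pop[, gi] <- single_flip_descent(pop[, gi], r_sub)
      costs[gi] <- polarity_cost_population(pop[, gi, drop = FALSE], r_sub)
      if (costs[gi] < best_cost - 1e-15) {
        best_cost <- costs[gi]
        best <- pop[, gi]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
    }
    if (best[1] < 0) best <- -best
    list(signs = as.numeric(best), cost = best_cost)
  })
}

# Greedy 1-opt descent: flipping entry i changes the cost by
# 2 s_i ((r s)_i - r_ii s_i); flip the best improving entry until none.
single_flip_descent <- function(s, r) {
  repeat {
    g <- as.numeric(r %*% s)
    delta <- 2 * s * (g - diag(r) * s)
    i <- which.min(delta)
    if (delta[i] >= -1e-12) break
    s[i] <- -s[i]
  }
  if (s[1] < 0) s <- -s
  s
}

tournament_pick <- function(costs) {
  ij <- sample.int(length(costs), 2L, replace = TRUE)
  ij[which.min(costs[ij])]
}

# Greedy seed: breadth-first sign propagation over the maximum-|r| spanning
# tree (computed as the minimum spanning tree of the distance 1 - |r|).
spanning_tree_signs <- function(r) {
  m <- nrow(r)
  if (m == 2L) return(c(1, if (r[1, 2] < 0) -1 else 1))
  adj <- unclass(ape::mst(stats::as.dist(1 - abs(r))))
  s <- numeric(m)
  s[1] <- 1
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[v, ] > 0 & s == 0)
    for (w in nb) {
      s[w] <- s[v] * (if (r[v, w] < 0) -1 else 1)
      queue <- c(queue, w)
    }
  }
  s[s == 0] <- 1   # disconnected safety; mst is always connected though
  s
}

# Dispatch: exact solver for small clusters, GA above the cap.
solve_polarity <- function(r_sub, cap = 15L, rng_seed = 1L) {
  if (nrow(r_sub) <= cap) solve_polarity_brute(r_sub, cap = cap)
  else solve_polarity_ga(r_sub, rng_seed = rng_seed)
}
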