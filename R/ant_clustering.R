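#' Parameters for ant-colony clustering
#'
#' Settings for the pheromone-driven clustering of points (here, lncRNA
#' association profiles). An ant at point i considers moving to cluster
#' center j with probability proportional to `T_ij^alpha * eta_ij^beta`,
#' where `T_ij` is the accumulated pheromone on the path from point i to
#' center j and `eta_ij = 1/d_ij` is the visibility (reciprocal Euclidean
#' distance). Pheromone evaporates at rate `rho_evap` and grows by a deposit
#' `Q/d` each cycle.
#'
#' Customary ranges are `alpha, beta` in (0,5), `rho_evap` in (0.1,0.99) and
#' `Q` in (1,10000); values outside them trigger a warning but only values
#' that break normalisation (non-positive where positivity is required) are
#' errors.
#'
#' @param r cluster radius used to lay down the initial pheromone
#'   (`T_ij = 1` iff `d_ij <= r`). `NULL` (default) means the median of all
#'   pairwise point distances, resolved when clustering starts.
#' @param p0 exploitation threshold in (0,1): the probability, per ant
#'   decision, of joining the best cluster outright (the pseudo-random
#'   proportional rule); with probability `1 - p0` the cluster is sampled
#'   from the transition distribution instead.
#' @param alpha pheromone importance exponent.
#' @param beta visibility (heuristic) importance exponent.
#' @param rho_evap pheromone evaporation rate in (0,1).
#' @param Q pheromone deposit constant (> 0); larger values accumulate
#'   pheromone faster and speed convergence.
#' @param max_iter maximum number of assign/update cycles.
#' @param mutation_rate probability, per cycle, of attempting one random
#'   single-point reassignment (the mutation refinement).
#' @param seed integer RNG seed; all stochastic choices (initial center,
#'   mutation draws) come from one generator seeded with it.
#' @param eps guard for zero distances in visibility and pheromone deposits.
#' @return A list of class `ant_params`.
#' @export
ant_params <- function(r = NULL, p0 = 0.7, alpha = 1, beta = 2,
                       rho_evap = 0.5, Q = 100, max_iter = 100,
                       mutation_rate = 0.2, seed = 1L, eps = 1e-12) {
  stopifnot(is.null(r) || r > 0, p0 > 0, max_iter >= 1,
            mutation_rate >= 0, mutation_rate <= 1, eps > 0)
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be nonnegative")
  if (rho_evap <= 0 || rho_evap > 1) {
    stop("'rho_evap' must lie in (0, 1]")
  }
  if (Q <= 0) stop("'Q' must be positive")
  if (alpha >= 5) warning("'alpha' outside the customary range (0, 5)")
  if (beta >= 5) warning("'beta' outside the customary range (0, 5)")
  if (rho_evap < 0.1 || rho_evap > 0.99) {
    warning("'rho_evap' outside the customary range (0.1, 0.99)")
  }
  if (Q <= 1 || Q >= 10000) {
    warning("'Q' outside the customary range (1, 10000)")
  }
  structure(list(r = r, p0 = p0, alpha = alpha, beta = beta,
                 rho_evap = rho_evap, Q = Q, max_iter = as.integer(max_iter),
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 eps = eps),
            class = "ant_params")
}

#' Euclidean distance between two vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  sqrt(sum((x - y)^2))
}

#' Visibility (reciprocal distance) heuristic
#'
#' `eta = 1/d`, with `d` floored at `eps` so a point coinciding with a
#' center yields a large finite visibility instead of dividing by zero.
#'
#' @param d nonnegative distance(s).
#' @param eps positive floor for `d`.
#' @return `1 / pmax(d, eps)`.
#' @export
visibility <- function(d, eps = 1e-12) {
  stopifnot(all(d >= 0), eps > 0)
  1 / pmax(d, eps)
}

# n x k matrix of Euclidean distances from each point (row) to each center.
point_center_distances <- function(points, centers) {
  pc <- tcrossprod(points, centers)                 # n x k
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") - 2 * pc
  sqrt(pmax(d2, 0))
}

#' Initial pheromone matrix
#'
#' The pheromone on the path from point i to center j starts at 1 when the
#' point lies within the cluster radius (`d_ij <= r`, boundary inclusive)
#' and 0 otherwise. After initialisation the pheromone evolves only through
#' [update_pheromone()].
#'
#' @param points n x d point matrix.
#' @param centers k x d center matrix.
#' @param r cluster radius (> 0).
#' @return n x k binary pheromone matrix.
#' @export
init_pheromone <- function(points, centers, r) {
  stopifnot(r > 0)
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  (point_center_distances(points, centers) <= r) * 1
}

#' Transition probabilities of one ant over the cluster centers
#'
#' `p_j = T_j^alpha * eta_j^beta / sum_j T_j^alpha * eta_j^beta`. When every
#' product is zero there is no admissible transition and an error is raised;
#' [assign_points()] catches this case and seeds a new cluster instead.
#'
#' @param T_row length-k nonnegative pheromone row.
#' @param eta_row length-k nonnegative visibility row.
#' @param alpha,beta importance exponents.
#' @return length-k probability vector summing to 1.
#' @export
transition_probabilities <- function(T_row, eta_row, alpha, beta) {
  if (length(T_row) != length(eta_row)) stop("length mismatch")
  stopifnot(all(T_row >= 0), all(eta_row >= 0))
  w <- T_row^alpha * eta_row^beta
  s <- sum(w)
  if (s == 0) stop("no admissible transition: all pheromone-visibility products are zero")
  w / s
}

#' Cluster centers as member means
#'
#' Each center is the arithmetic mean of its member points; clusters that
#' lost all members are dropped and the remaining cluster indices compacted
#' to 1..k'.
#'
#' @param points n x d point matrix.
#' @param assignments length-n integer cluster labels.
#' @return A list with `centers` (k' x d) and `assignments` (compacted).
#' @export
update_centers <- function(points, assignments) {
  points <- as.matrix(points)
  keep <- sort(unique(assignments))
  new_lab <- match(assignments, keep)
  k <- length(keep)
  centers <- matrix(0, k, ncol(points))
  for (j in seq_len(k)) {
    centers[j, ] <- colMeans(points[new_lab == j, , drop = FALSE])
  }
  list(centers = centers, assignments = new_lab)
}

#' Pheromone update rule
#'
#' `T'_ij = (1 - rho_evap) * T_ij + Q / max(d_ij, eps)`: the old trail
#' evaporates and every point deposits pheromone on the path to every
#' current center, inversely to its distance.
#'
#' @param pheromone n x k nonnegative pheromone matrix.
#' @param distances n x k matrix of point-to-center distances.
#' @param params an [ant_params()] object (uses `rho_evap`, `Q`, `eps`).
#' @return Updated n x k pheromone matrix.
#' @export
update_pheromone <- function(pheromone, distances, params) {
  stopifnot(all(dim(pheromone) == dim(distances)), all(distances >= 0))
  (1 - params$rho_evap) * pheromone + params$Q / pmax(distances, params$eps)
}

#' Clustering objective: mean squared distance to own center
#'
#' `F = (1/n) * sum_i ||point_i - center_{assign(i)}||^2`, the mean square
#' error of the sample points to their cluster centers. This is the quantity
#' the mutation step tries to lower.
#'
#' @param points n x d point matrix.
#' @param state a `cluster_state` (needs `assignments` and `centers`).
#' @return Nonnegative scalar.
#' @export
objective_F <- function(points, state) {
  points <- as.matrix(points)
  diff <- points - state$centers[state$assignments, , drop = FALSE]
  mean(rowSums(diff^2))
}

new_cluster_state <- function(assignments, centers, pheromone,
                              objective = NA_real_,
                              best_objective = Inf, iterations = 0L) {
  structure(list(assignments = as.integer(assignments), centers = centers,
                 pheromone = pheromone, objective = objective,
                 best_objective = best_objective,
                 iterations = as.integer(iterations)),
            class = "cluster_state")
}

#' @export
print.cluster_state <- function(x, ...) {
  cat("cluster_state:", length(x$assignments), "points in",
      nrow(x$centers), "clusters; F =", format(x$objective),
      "(best", format(x$best_objective), "after",
      x$iterations, "iterations)\n")
  invisible(x)
}

#' One assignment pass of the ant colony
#'
#' Each point in turn computes its transition probabilities over the current
#' centers and applies the pseudo-random proportional rule of ant colony
#' systems: with probability `p0` the ant exploits, joining the
#' highest-probability cluster; otherwise it explores, sampling the cluster
#' from the transition distribution. A point seeds a new cluster at its own
#' position only when it has no admissible transition at all — every
#' pheromone-visibility product is zero, i.e. it lies beyond the
#' radius-supported paths — and the new cluster's pheromone column is
#' laid down by the radius rule of [init_pheromone()]. After the pass,
#' centers are recomputed as member means, empty clusters dropped, and
#' pheromone columns compacted to match.
#'
#' @param points n x d point matrix.
#' @param state current `cluster_state`.
#' @param params an [ant_params()] object with `r` resolved.
#' @return Updated `cluster_state`.
#' @export
assign_points <- function(points, state, params) {
  points <- as.matrix(points)
  n <- nrow(points)
  centers <- state$centers
  pher <- state$pheromone
  assignments <- state$assignments
  for (i in seq_len(n)) {
    d <- point_center_distances(points[i, , drop = FALSE], centers)[1, ]
    eta <- visibility(d, params$eps)
    w <- pher[i, ]^params$alpha * eta^params$beta
    s <- sum(w)
    if (s > 0) {
      p <- w / s
      j <- if (stats::runif(1) <= params$p0 || length(p) == 1L) {
        which.max(p)
      } else {
        sample.int(length(p), 1L, prob = p)
      }
      assignments[i] <- j
      next
    }
    # no admissible transition: seed a new cluster here
    centers <- rbind(centers, points[i, ])
    pher <- cbind(pher,
                  init_pheromone(points, centers[nrow(centers), , drop = FALSE],
                                 params$r))
    assignments[i] <- nrow(centers)
  }
  upd <- update_centers(points, assignments)
  keep <- sort(unique(assignments))
  new_cluster_state(upd$assignments, upd$centers,
                    pher[, keep, drop = FALSE],
                    objective = state$objective,
                    best_objective = state$best_objective,
                    iterations = state$iterations)
}

#' Mutation refinement step
#'
#' With probability `mutation_rate`, one uniformly chosen point is
#' tentatively reassigned to a uniformly chosen different cluster and the
#' objective of the mutated configuration (`F_temp`) is computed. The
#' mutation is accepted only when `F_temp` beats the best objective seen so
#' far (`F_min`), which makes the best objective nonincreasing over any
#' sequence of calls. A no-op when fewer than two clusters exist.
#'
#' @inheritParams assign_points
#' @return A `cluster_state`, mutated or unchanged.
#' @export
mutate_state <- function(points, state, params) {
  k <- nrow(state$centers)
  if (k < 2L || params$mutation_rate == 0) return(state)
  if (stats::runif(1) >= params$mutation_rate) return(state)
  points <- as.matrix(points)
  n <- nrow(points)
  i <- sample.int(n, 1L)
  others <- which(seq_len(k) != state$assignments[i])
  j <- others[sample.int(length(others), 1L)]
  trial <- state$assignments
  trial[i] <- j
  upd <- update_centers(points, trial)
  f_temp <- objective_F(points, list(assignments = upd$assignments,
                                     centers = upd$centers))
  if (f_temp < state$best_objective) {
    keep <- sort(unique(trial))
    new_cluster_state(upd$assignments, upd$centers,
                      state$pheromone[, keep, drop = FALSE],
                      objective = f_temp, best_objective = f_temp,
                      iterations = state$iterations)
  } else {
    state
  }
}

#' Ant-colony clustering with pheromone dynamics and mutation
#'
#' Clusters the rows of `points` (for this package, lncRNA association
#' profiles). One cluster is seeded at a uniformly drawn point and the
#' initial pheromone is laid down by the radius rule; the colony then loops
#' assignment, center update, pheromone evaporation/deposit and the mutation
#' refinement until the assignment vector is identical on two consecutive
#' iterations or `max_iter` is reached. The number of clusters is not fixed
#' in advance: it grows through the `p0` rule of [assign_points()] and
#' shrinks as empty clusters are dropped.
#'
#' Runs are deterministic given `params$seed`. Internally points are
#' processed in a canonical (lexicographic) order before the seed is
#' applied, so the result is invariant to permutations of the input rows up
#' to cluster relabelling. Because the exploration regime keeps sampling,
#' the configuration returned is the best one encountered — the assignment
#' and centers achieving `best_objective` (the running minimum `F_min` of
#' the objective), not the last sampled state.
#'
#' @param points n x d numeric matrix, one point per row.
#' @param params an [ant_params()] object.
#' @return A `cluster_state` with `assignments` (in input row order),
#'   `centers`, `pheromone`, `objective` (= `best_objective`, the objective
#'   of the returned configuration) and `iterations` used.
#' @examples
#' pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' run_clustering(pts, ant_params(seed = 42))
#' @export
run_clustering <- function(points, params = ant_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1L)
  if (is.null(params$r)) params$r <- default_radius(points)
  withr::local_seed(params$seed)
  ord <- do.call(order, as.data.frame(points))
  pts <- points[ord, , drop = FALSE]

  i0 <- sample.int(n, 1L)
  centers <- pts[i0, , drop = FALSE]
  state <- new_cluster_state(rep(1L, n), centers,
                             init_pheromone(pts, centers, params$r))
  prev <- NULL
  iterations <- 0L
  best <- list(assignments = state$assignments, centers = state$centers,
               pheromone = state$pheromone, objective = Inf)
  for (it in seq_len(params$max_iter)) {
    iterations <- it
    state <- assign_points(pts, state, params)
    dists <- point_center_distances(pts, state$centers)
    state$pheromone <- update_pheromone(state$pheromone, dists, params)
    state$objective <- objective_F(pts, state)
    state$best_objective <- min(state$best_objective, state$objective)
    state <- mutate_state(pts, state, params)
    if (state$objective <= best$objective) {
      best <- list(assignments = state$assignments, centers = state$centers,
                   pheromone = state$pheromone, objective = state$objective)
    }
    if (!is.null(prev) && identical(state$assignments, prev)) break
    prev <- state$assignments
  }
  assignments <- integer(n)
  assignments[ord] <- best$assignments
  pher <- best$pheromone
  pher[ord, ] <- best$pheromone
  new_cluster_state(assignments, best$centers, pher,
                    objective = best$objective,
                    best_objective = state$best_objective,
                    iterations = iterations)
}

#' Default cluster radius: median pairwise distance
#'
#' @param points n x d point matrix.
#' @return Median of all pairwise Euclidean distances (a small positive
#'   fallback when all points coincide).
#' @export
default_radius <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(1)
  r <- stats::median(stats::dist(points))
  if (r <= 0) 1e-6 else r
}
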