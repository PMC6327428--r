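test_that("euclidean distance matches the summation oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:5, 1:5), 0)
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")
  withr::local_seed(7)
  x <- rnorm(10); y <- rnorm(10)
  oracle <- sqrt(sum(vapply(seq_along(x),
                            function(k) abs(x[k] - y[k])^2, 0)))
  expect_equal(euclidean_distance(x, y), oracle, tolerance = 1e-12)
})

test_that("visibility is the guarded reciprocal distance and is monotone", {
  expect_equal(visibility(2), 0.5)
  expect_equal(visibility(0, eps = 1e-12), 1e12)
  d <- sort(runif(20, 0, 5))
  expect_true(all(diff(visibility(d)) <= 0))
})

test_that("initial pheromone follows the inclusive radius rule", {
  pts <- rbind(c(0, 0), c(3, 4), c(6, 8))
  centers <- rbind(c(0, 0))
  ph <- init_pheromone(pts, centers, r = 5)
  expect_equal(ph[, 1], c(1, 1, 0))   # d = 5 is inside (boundary inclusive)
  expect_true(all(init_pheromone(pts, centers, r = 100) == 1))
})

test_that("transition probabilities normalise and weigh pheromone against visibility", {
  expect_equal(transition_probabilities(3, 7, 1, 2), 1)
  expect_equal(transition_probabilities(rep(0, 4), rep(2, 4), 0, 0),
               rep(0.25, 4))
  expect_equal(transition_probabilities(c(1, 1), c(2, 1), 1, 1),
               c(2 / 3, 1 / 3))
  expect_error(transition_probabilities(c(0, 0), c(1, 1), 1, 2),
               "no admissible")
  withr::local_seed(11)
  for (i in 1:20) {
    p <- transition_probabilities(runif(5), runif(5) + 0.1,
                                  runif(1, 0.1, 3), runif(1, 0.1, 3))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("centers are member means and empty clusters are compacted", {
  pts <- rbind(c(0, 0), c(2, 2), c(5, 5))
  upd <- update_centers(pts, c(1, 1, 3))
  expect_equal(upd$centers[1, ], c(1, 1))
  expect_equal(upd$centers[2, ], c(5, 5))     # index 3 compacted to 2
  expect_equal(upd$assignments, c(1L, 1L, 2L))
  withr::local_seed(5)
  pts <- matrix(rnorm(40), 10, 4)
  lab <- sample(3, 10, replace = TRUE)
  upd <- update_centers(pts, lab)
  for (j in sort(unique(upd$assignments))) {
    expect_equal(upd$centers[j, ],
                 colMeans(pts[upd$assignments == j, , drop = FALSE]))
  }
})

test_that("pheromone update evaporates and deposits, with the analytic fixed point", {
  p <- suppressWarnings(ant_params(rho_evap = 1, Q = 2))
  expect_equal(update_pheromone(matrix(5), matrix(2), p), matrix(1))
  p <- suppressWarnings(ant_params(rho_evap = 0.5, Q = 1))
  expect_equal(update_pheromone(matrix(2), matrix(2), p), matrix(1.5))
  # T* = Q / (rho * d) is stationary
  p <- ant_params(rho_evap = 0.4, Q = 7)
  d <- matrix(c(0.5, 2, 9), 1)
  t_star <- p$Q / (p$rho_evap * d)
  expect_equal(update_pheromone(t_star, d, p), t_star, tolerance = 1e-12)
  # stays nonnegative and finite under repeated application
  tt <- matrix(runif(12), 3, 4)
  dd <- matrix(runif(12, 0, 3), 3, 4)
  for (i in 1:50) tt <- update_pheromone(tt, dd, p)
  expect_true(all(tt >= 0) && all(is.finite(tt)))
})

test_that("objective is the mean squared distance to the own center", {
  pts <- rbind(c(-2), c(2))
  st <- list(assignments = c(1L, 1L), centers = matrix(0, 1, 1))
  expect_equal(objective_F(pts, st), 4)
  st2 <- list(assignments = c(1L, 2L), centers = pts)
  expect_equal(objective_F(pts, st2), 0)
  withr::local_seed(8)
  pts <- matrix(rnorm(30), 10, 3)
  lab <- sample(2, 10, replace = TRUE)
  upd <- update_centers(pts, lab)
  oracle <- mean(vapply(1:10, function(i)
    sum((pts[i, ] - upd$centers[upd$assignments[i], ])^2), 0))
  expect_equal(objective_F(pts, list(assignments = upd$assignments,
                                     centers = upd$centers)),
               oracle, tolerance = 1e-12)
})

test_that("mutation only ever accepts configurations that beat the best objective", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  # deliberately mis-assigned: one far point grouped with the near pair
  st <- update_centers(pts, c(1L, 1L, 1L, 2L))
  state <- structure(list(assignments = st$assignments, centers = st$centers,
                          pheromone = matrix(1, 4, 2),
                          objective = objective_F(pts, st),
                          best_objective = objective_F(pts, st),
                          iterations = 0L), class = "cluster_state")
  p0 <- ant_params(mutation_rate = 0)
  expect_identical(mutate_state(pts, state, p0), state)

  # optimal objective by exhausting all 2-cluster assignments
  best_f <- Inf
  for (code in 0:(2^4 - 1)) {
    lab <- as.integer(intToBits(code)[1:4]) + 1L
    if (length(unique(lab)) < 2) next
    upd <- update_centers(pts, lab)
    best_f <- min(best_f, objective_F(pts, list(assignments = upd$assignments,
                                                centers = upd$centers)))
  }
  p1 <- ant_params(mutation_rate = 1)
  withr::local_seed(21)
  hist <- numeric(0)
  for (i in 1:300) {
    state <- mutate_state(pts, state, p1)
    hist <- c(hist, state$best_objective)
  }
  expect_true(all(diff(hist) <= 0))          # F_min nonincreasing
  expect_equal(state$best_objective, best_f) # the improving move was found
})

test_that("well-separated pairs form two clusters and identical points one", {
  pts <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  st <- run_clustering(pts, ant_params(r = 1, p0 = 0.5, seed = 4))
  expect_equal(nrow(st$centers), 2)
  expect_equal(st$assignments[1], st$assignments[2])
  expect_equal(st$assignments[3], st$assignments[4])
  expect_true(st$assignments[1] != st$assignments[3])

  same <- matrix(1, 5, 3)
  st <- run_clustering(same, ant_params(seed = 2))
  expect_equal(nrow(st$centers), 1)
  expect_equal(st$objective, 0)
})

test_that("clustering a single point yields one zero-error cluster", {
  st <- run_clustering(matrix(c(1, 2), 1, 2), ant_params(seed = 1))
  expect_equal(nrow(st$centers), 1)
  expect_equal(st$objective, 0)
  expect_equal(st$assignments, 1L)
})

test_that("separable Gaussian blobs are recovered and runs are reproducible", {
  b <- generate_blobs(n_per_cluster = 30, dims = 2, n_clusters = 3,
                      center_sep = 10, sigma = 0.5, seed = 42)
  st <- run_clustering(b$points, ant_params(seed = 42))
  expect_gte(adjusted_rand_index(st$assignments, b$labels), 0.9)
  st2 <- run_clustering(b$points, ant_params(seed = 42))
  expect_identical(st$assignments, st2$assignments)
  expect_equal(st$best_objective, st2$best_objective)
})

test_that("clustering is invariant to point order up to relabelling", {
  b <- generate_blobs(n_per_cluster = 15, seed = 6)
  st <- run_clustering(b$points, ant_params(seed = 6))
  perm <- withr::with_seed(99, sample(nrow(b$points)))
  st_p <- run_clustering(b$points[perm, ], ant_params(seed = 6))
  expect_equal(adjusted_rand_index(st$assignments[perm], st_p$assignments), 1)
})

test_that("parameter ranges are soft-warned and hard errors stop division blowups", {
  expect_warning(ant_params(alpha = 6), "customary")
  expect_warning(ant_params(Q = 0.5), "customary")
  expect_error(ant_params(Q = -1), "positive")
  expect_error(ant_params(rho_evap = 0), "rho_evap")
  expect_silent(ant_params())
})
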