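# Shared fixtures, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_net <- function() {
  interaction_network(matrix(c(1, 0, 1, 1), 2, 2),
                      c("L1", "L2"), c("P1", "P2"))
}

random_net <- function(n, m, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    adj <- matrix(rbinom(n * m, 1, p), n, m)
    adj[sample(n, 1), ] <- pmax(adj[sample(n, 1), ], c(1, rep(0, m - 1)))
    interaction_network(adj, paste0("L", seq_len(n)), paste0("P", seq_len(m)))
  })
}

# Random row-stochastic matrix with zero diagonal.
random_row_stochastic <- function(n, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * n), n, n)
    diag(W) <- 0
    W / rowSums(W)
  })
}

expect_network_equal <- function(a, b) {
  expect_identical(a$lncrna_ids, b$lncrna_ids)
  expect_identical(a$protein_ids, b$protein_ids)
  expect_equal(unname(a$adjacency), unname(b$adjacency))
}
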