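#' Parameters for the baseline predictors
#'
#' @param restart_prob restart probability `c` in (0, 1] for random walk
#'   with restart.
#' @param tol convergence tolerance on the max-abs change of the walk
#'   distribution.
#' @param max_iter maximum number of iterations.
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(restart_prob = 0.7, tol = 1e-10,
                            max_iter = 1000) {
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "baseline_params")
}

#' Random walk with restart on the bipartite graph
#'
#' Builds the full (n + m) x (n + m) bipartite adjacency, column-normalises
#' it into a transition matrix T, and for each lncRNA seed i iterates
#' `s <- (1 - c) * T %*% s + c * e_i` to the stationary distribution. The
#' score of pair (i, j) is the stationary probability mass on protein j when
#' seeding at lncRNA i. All seeds are propagated simultaneously as columns
#' of one matrix.
#'
#' @param net an [interaction_network()].
#' @param params a [baseline_params()] object.
#' @return n x m score matrix (lncRNA seeds by proteins).
#' @export
rwr_scores <- function(net, params = baseline_params()) {
  stopifnot(inherits(net, "interaction_network"))
  A <- net$adjacency
  n <- nrow(A)
  m <- ncol(A)
  full <- rbind(cbind(matrix(0, n, n), A),
                cbind(t(A), matrix(0, m, m)))
  cs <- colSums(full)
  cs[cs == 0] <- 1                     # isolated column: no outflow
  Tm <- sweep(full, 2, cs, "/")
  cc <- params$restart_prob
  E <- rbind(diag(n), matrix(0, m, n)) # restart vectors, one column per seed
  S <- E
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    S_new <- (1 - cc) * (Tm %*% S) + cc * E
    if (max(abs(S_new - S)) < params$tol) {
      S <- S_new
      converged <- TRUE
      break
    }
    S <- S_new
  }
  if (!converged) warning("random walk with restart did not converge")
  scores <- t(S[n + seq_len(m), , drop = FALSE])
  dimnames(scores) <- dimnames(A)
  scores
}

#' Bipartite network inference by two-phase resource allocation
#'
#' LPBNI-style scoring: for query lncRNA i the unit resources sitting on its
#' interacting proteins first spread back to lncRNAs, each protein dividing
#' its resource equally among its neighbor lncRNAs (division by protein
#' degree), then spread forward to proteins, each lncRNA dividing equally
#' among its neighbor proteins (division by lncRNA degree). The score of
#' pair (i, j) is the final resource on protein j. Resource is conserved:
#' row i of the score matrix sums to the degree of lncRNA i.
#'
#' @param net an [interaction_network()].
#' @return n x m score matrix.
#' @export
lpbni_scores <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  A <- net$adjacency
  kp <- colSums(A)
  kl <- rowSums(A)
  inv_kp <- ifelse(kp > 0, 1 / kp, 0)
  inv_kl <- ifelse(kl > 0, 1 / kl, 0)
  # phase 1: protein -> lncRNA, phase 2: lncRNA -> protein, all queries at once
  G <- A %*% (t(A) * inv_kp)           # n x n: resource received by lncRNAs
  scores <- sweep(G, 2, inv_kl, "*") %*% A
  dimnames(scores) <- dimnames(A)
  scores
}
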