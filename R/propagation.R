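#' Parameters for label propagation
#'
#' Label propagation diffuses the known interaction labels of each protein
#' over the lncRNA similarity graph: at every step a node absorbs its
#' neighbors' labels with probability `rho_prop` and retains its initial
#' label with probability `1 - rho_prop`. `rho_prop = 0.6` gives the best
#' prediction accuracy in the source experiments and is the default;
#' `rho_prop < 1` guarantees convergence when W is row-stochastic.
#'
#' @param rho_prop absorption probability in `[0, 1)`.
#' @param tol convergence tolerance on the max-abs change between iterates.
#' @param max_iter maximum number of iterations.
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(rho_prop = 0.6, tol = 1e-8, max_iter = 1000) {
  stopifnot(rho_prop >= 0, rho_prop < 1, tol > 0, max_iter >= 1)
  structure(list(rho_prop = rho_prop, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "propagation_params")
}

check_propagation_inputs <- function(W, M) {
  W <- as.matrix(W)
  M <- as.matrix(M)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (nrow(M) != nrow(W)) stop("M must have one row per W node")
  rs <- rowSums(W)
  bad <- rs != 0 & abs(rs - 1) > 1e-6
  if (any(bad)) {
    stop("W is not row-stochastic: row ", which(bad)[1], " sums to ",
         rs[which(bad)[1]])
  }
  list(W = W, M = M)
}

#' Label propagation over the lncRNA similarity graph
#'
#' Iterates `P^t = rho * W %*% P^{t-1} + (1 - rho) * M` from `P^0 = M` until
#' the max-abs elementwise change drops below `tol` or `max_iter` is
#' reached. Column k of M holds the known associations of protein k over all
#' lncRNAs (its initial labels); the fixed point blends each lncRNA's own
#' labels with those of its similarity neighbors. Convergence is geometric
#' with ratio at most `rho` because W is row-stochastic.
#'
#' @param W n x n row-stochastic lncRNA similarity matrix (rows may be all
#'   zero for isolated nodes, whose scores then reduce to `(1 - rho) * M`).
#' @param M n x m binary association matrix (or an [interaction_network()]).
#' @param params a [propagation_params()] object.
#' @return n x m score matrix with attributes `iterations` (number of
#'   iterations run) and `converged` (logical). A warning is issued and the
#'   partial result returned if `max_iter` is hit first.
#' @seealso [closed_form()] for the exact fixed point.
#' @export
propagate <- function(W, M, params = propagation_params()) {
  if (inherits(M, "interaction_network")) M <- M$adjacency
  inp <- check_propagation_inputs(W, M)
  W <- inp$W
  M <- inp$M
  rho <- params$rho_prop
  P <- M
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    iters <- it
    P_new <- rho * (W %*% P) + (1 - rho) * M
    delta <- max(abs(P_new - P))
    P <- P_new
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("label propagation did not converge in ", params$max_iter,
            " iterations; returning partial result")
  }
  dimnames(P) <- dimnames(M)
  attr(P, "iterations") <- iters
  attr(P, "converged") <- converged
  P
}

#' Closed-form fixed point of label propagation
#'
#' Solves the stationary equation `P = rho * W %*% P + (1 - rho) * M`
#' directly: `P* = (1 - rho) * (I - rho W)^{-1} M`. Because W is
#' row-stochastic and `rho < 1`, the system matrix is strictly diagonally
#' dominant and the solve cannot be singular. Used as the analytic oracle
#' for [propagate()].
#'
#' @inheritParams propagate
#' @param rho_prop absorption probability in `[0, 1)`.
#' @return n x m exact fixed-point score matrix.
#' @export
closed_form <- function(W, M, rho_prop = 0.6) {
  if (inherits(M, "interaction_network")) M <- M$adjacency
  stopifnot(rho_prop >= 0, rho_prop < 1)
  inp <- check_propagation_inputs(W, M)
  n <- nrow(inp$W)
  P <- (1 - rho_prop) * solve(diag(n) - rho_prop * inp$W, inp$M)
  dimnames(P) <- dimnames(inp$M)
  P
}

#' Rank candidate interactions from a score matrix
#'
#' Flattens a score matrix into a ranked table of lncRNA-protein pairs,
#' optionally dropping pairs already known in the training network (the
#' usual novel-prediction view).
#'
#' @param scores n x m score matrix, dimnames giving the ids.
#' @param net the training [interaction_network()] whose known pairs should
#'   be excluded; `NULL` keeps every pair.
#' @return A `data.frame` with columns `lncrna`, `protein`, `score`, `rank`,
#'   sorted by decreasing score (ties broken by lncRNA then protein index
#'   for determinism).
#' @export
rank_predictions <- function(scores, net = NULL) {
  idx <- which(matrix(TRUE, nrow(scores), ncol(scores)), arr.ind = TRUE)
  if (!is.null(net)) {
    stopifnot(inherits(net, "interaction_network"),
              all(dim(net$adjacency) == dim(scores)))
    idx <- idx[net$adjacency[idx] == 0, , drop = FALSE]
  }
  s <- scores[idx]
  ord <- order(-s, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(
    lncrna = rownames(scores)[idx[, 1]],
    protein = colnames(scores)[idx[, 2]],
    score = scores[idx],
    rank = seq_len(nrow(idx)),
    stringsAsFactors = FALSE
  )
}
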