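#' Parameters for linear neighborhood similarity
#'
#' @param k_neighbors number of nearest neighbors each point is
#'   reconstructed from. `NULL` (default) resolves to `min(10, n - 1)` when
#'   the profiles are seen.
#' @param ridge small nonnegative Tikhonov regulariser added to the local
#'   Gram matrix; stabilises the reconstruction when neighbors are
#'   (near-)collinear.
#' @return A list of class `lns_params`.
#' @export
lns_params <- function(k_neighbors = NULL, ridge = 1e-6) {
  stopifnot(is.null(k_neighbors) || k_neighbors >= 1, ridge >= 0)
  structure(list(k_neighbors = k_neighbors, ridge = ridge),
            class = "lns_params")
}

# Exact active-set solver for
#   min_w ||x - t(N) %*% w||^2 + ridge * ||w||^2   s.t. w >= 0, sum(w) = 1
# with N the k x d neighbor matrix (neighbors as rows). k is small (the
# neighborhood size), so repeated dense solves are cheap. The equality
# constraint is handled through its Lagrange multiplier; bound constraints
# by dropping the most negative coordinate / re-adding the most violating
# one until the KKT conditions hold.
simplex_reconstruction <- function(N, x, ridge) {
  k <- nrow(N)
  if (k == 1L) return(1)
  G <- tcrossprod(N) + ridge * diag(k)
  a <- drop(N %*% x)
  support <- seq_len(k)
  w <- rep(1 / k, k)
  for (pass in seq_len(4L * k + 8L)) {
    ks <- length(support)
    kkt <- rbind(cbind(2 * G[support, support, drop = FALSE], rep(1, ks)),
                 c(rep(1, ks), 0))
    sol <- tryCatch(solve(kkt, c(2 * a[support], 1)),
                    error = function(e) NULL)
    if (is.null(sol)) break
    ws <- sol[seq_len(ks)]
    lambda <- sol[ks + 1L]
    if (any(ws < -1e-12)) {
      support <- support[-which.min(ws)]
      if (length(support) == 0L) break
      next
    }
    w <- rep(0, k)
    w[support] <- pmax(ws, 0)
    grad <- 2 * (drop(G %*% w) - a) + lambda
    outside <- setdiff(seq_len(k), support)
    violated <- outside[grad[outside] < -1e-9]
    if (length(violated) == 0L) return(w / sum(w))
    support <- sort(c(support, violated[which.min(grad[violated])]))
  }
  w <- pmax(w, 0)
  w / sum(w)
}

#' Linear neighborhood similarity (LNS) weights
#'
#' Builds the row-stochastic similarity matrix W used by label propagation.
#' Each point (an association profile) is reconstructed as a convex
#' combination of its `k_neighbors` nearest neighbors by Euclidean distance:
#' row i of W solves
#' `min_w ||x_i - sum_j w_j x_j||^2 + ridge * ||w||^2` over the simplex
#' (`w_j >= 0`, `sum w_j = 1`, support restricted to the neighborhood), with
#' zeros elsewhere and a zero diagonal. Nearest-neighbor ties break by node
#' index, so the construction is deterministic. An all-zero profile cannot
#' be reconstructed meaningfully and receives uniform weights over its
#' neighborhood, with a warning.
#'
#' @param profiles n x d numeric matrix, one profile per row (row names, if
#'   present, become node ids).
#' @param params an [lns_params()] object.
#' @return n x n row-stochastic similarity matrix with zero diagonal.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' W <- lns_weights(X, lns_params(k_neighbors = 3))
#' rowSums(W)
#' @export
lns_weights <- function(profiles, params = lns_params()) {
  X <- as.matrix(profiles)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 profiles")
  k <- params$k_neighbors
  if (is.null(k)) k <- min(10L, n - 1L)
  if (k >= n) stop("'k_neighbors' must be at most n - 1 = ", n - 1L)
  D <- point_center_distances(X, X)
  W <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  zero_rows <- which(rowSums(abs(X)) == 0)
  if (length(zero_rows)) {
    warning(length(zero_rows), " all-zero profile(s): uniform neighbor ",
            "weights assigned")
  }
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]          # order() breaks ties by index
    if (i %in% zero_rows) {
      W[i, nb] <- 1 / k
    } else {
      W[i, nb] <- simplex_reconstruction(X[nb, , drop = FALSE], X[i, ],
                                         params$ridge)
    }
  }
  diag(W) <- 0
  assert_row_stochastic(W)
  W
}

#' Check that a similarity matrix is row-stochastic
#'
#' Every row must be nonnegative and sum to 1 within `tol`, except rows of
#' an isolated node, which may be all zero. The diagonal must be zero.
#'
#' @param W n x n similarity matrix.
#' @param tol tolerance on row sums.
#' @return `W`, invisibly; errors otherwise.
#' @export
assert_row_stochastic <- function(W, tol = 1e-8) {
  if (any(W < 0)) stop("similarity matrix has negative entries")
  if (any(diag(W) != 0)) stop("similarity matrix has a nonzero diagonal")
  rs <- rowSums(W)
  bad <- rs != 0 & abs(rs - 1) > tol
  if (any(bad)) {
    stop("similarity rows not stochastic: row ", which(bad)[1],
         " sums to ", rs[which(bad)[1]])
  }
  invisible(W)
}

#' Enhance a similarity matrix with cluster structure
#'
#' Blends the LNS matrix with the partition found by ant-colony clustering:
#' `W' = normalize(delta * W_cross + W_within + gamma * B)`, where
#' `W_within` / `W_cross` are the within- and cross-cluster parts of W and
#' `B` is the uniform within-cluster kernel (`B_ij = 1/(|C_i| - 1)` for
#' same-cluster `j != i`, zero for singleton clusters). The additive kernel
#' lets cluster membership contribute similarity even between nodes the
#' sparse LNS reconstruction left unconnected, while `delta` damps
#' cross-cluster leakage; each nonzero row is renormalised to sum to 1,
#' preserving the row-stochasticity that label propagation requires.
#' `gamma = 0`, `delta = 1` leaves W unchanged (and the operation is then
#' idempotent).
#'
#' @param W n x n row-stochastic similarity matrix.
#' @param labels length-n cluster assignment vector.
#' @param gamma weight of the uniform within-cluster kernel, >= 0.
#' @param delta cross-cluster retention factor in `[0, 1]`.
#' @return Enhanced row-stochastic similarity matrix.
#' @export
enhance_with_clusters <- function(W, labels, gamma = 0.5, delta = 1.0) {
  stopifnot(length(labels) == nrow(W), gamma >= 0, delta >= 0, delta <= 1)
  same <- outer(labels, labels, "==")
  sizes <- as.numeric(table(labels)[as.character(labels)])
  B <- same / pmax(sizes - 1, 1)
  B[sizes == 1, ] <- 0
  diag(B) <- 0
  W2 <- W * ifelse(same, 1, delta) + gamma * B
  diag(W2) <- 0
  rs <- rowSums(W2)
  nz <- rs > 0
  W2[nz, ] <- W2[nz, , drop = FALSE] / rs[nz]
  assert_row_stochastic(W2)
  W2
}

#' Read/write a labelled similarity matrix as CSV
#'
#' @param W similarity matrix with node ids as dimnames.
#' @param path CSV file path.
#' @return `write_similarity_csv()` returns `path` invisibly;
#'   `read_similarity_csv()` returns the labelled matrix.
#' @export
write_similarity_csv <- function(W, path) {
  utils::write.csv(as.data.frame(W), path)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
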