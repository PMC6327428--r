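#' Specification of a synthetic block-structured bipartite network
#'
#' Emulates the cluster structure the pipeline assumes in real interaction
#' data: groups of lncRNAs that preferentially interact with matching groups
#' of proteins, plus sparse background edges. The defaults (100 lncRNAs x
#' 50 proteins, 5 blocks, within-block edge probability 0.30, background
#' 0.01) define the standard evaluation scenario used throughout the tests
#' and the acceptance script; they are sized so that a full repeated
#' cross-validation of the pipeline runs in minutes on one CPU.
#'
#' @param n_lncrna,n_protein node counts.
#' @param n_blocks number of matched lncRNA/protein blocks.
#' @param p_within edge probability inside a matched block pair.
#' @param p_background edge probability elsewhere
#'   (`p_background < p_within`).
#' @param seed integer RNG seed.
#' @return A list of class `block_network_spec`.
#' @export
block_network_spec <- function(n_lncrna = 100, n_protein = 50, n_blocks = 5,
                               p_within = 0.30, p_background = 0.01,
                               seed = 1L) {
  stopifnot(n_lncrna >= 1, n_protein >= 1,
            n_blocks >= 1, n_blocks <= min(n_lncrna, n_protein),
            p_background >= 0, p_background < p_within, p_within <= 1)
  structure(list(n_lncrna = as.integer(n_lncrna),
                 n_protein = as.integer(n_protein),
                 n_blocks = as.integer(n_blocks),
                 p_within = p_within, p_background = p_background,
                 seed = as.integer(seed)),
            class = "block_network_spec")
}

#' Generate a block-structured bipartite network
#'
#' lncRNAs and proteins are partitioned into `n_blocks` near-equal
#' contiguous groups; each lncRNA-protein pair receives an edge
#' independently with probability `p_within` when their blocks match and
#' `p_background` otherwise. Deterministic given `spec$seed`.
#'
#' @param spec a [block_network_spec()].
#' @return A list with `network` (an [interaction_network()]),
#'   `lncrna_blocks` and `protein_blocks` (integer block labels, the ground
#'   truth for clustering validation).
#' @export
generate_block_network <- function(spec = block_network_spec()) {
  stopifnot(inherits(spec, "block_network_spec"))
  lb <- cut(seq_len(spec$n_lncrna), spec$n_blocks, labels = FALSE)
  pb <- cut(seq_len(spec$n_protein), spec$n_blocks, labels = FALSE)
  prob <- ifelse(outer(lb, pb, "=="), spec$p_within, spec$p_background)
  adj <- withr::with_seed(
    spec$seed,
    matrix(stats::rbinom(length(prob), 1, prob), nrow(prob), ncol(prob))
  )
  net <- interaction_network(
    adj,
    sprintf("L%03d", seq_len(spec$n_lncrna)),
    sprintf("P%03d", seq_len(spec$n_protein))
  )
  list(network = net, lncrna_blocks = lb, protein_blocks = pb)
}

#' Generate separable Gaussian point clouds
#'
#' Isotropic Gaussian clusters around centers that are pairwise at least
#' `center_sep` apart (centers are drawn uniformly in a box and redrawn
#' until the separation holds). Deterministic given `seed`.
#'
#' @param n_per_cluster points per cluster.
#' @param dims dimensionality.
#' @param n_clusters number of clusters.
#' @param center_sep minimum pairwise center distance (> 0).
#' @param sigma isotropic standard deviation within each cluster (> 0).
#' @param seed integer RNG seed.
#' @return A list with `points` (matrix), `labels` (integer vector) and
#'   `centers` (the true cluster centers).
#' @export
generate_blobs <- function(n_per_cluster = 30, dims = 2, n_clusters = 3,
                           center_sep = 10, sigma = 0.5, seed = 1L) {
  stopifnot(center_sep > 0, sigma > 0, n_per_cluster >= 1,
            dims >= 1, n_clusters >= 1)
  withr::with_seed(as.integer(seed), {
    box <- center_sep * max(3, n_clusters)
    repeat {
      centers <- matrix(stats::runif(n_clusters * dims, 0, box),
                        n_clusters, dims)
      if (n_clusters == 1L ||
          min(stats::dist(centers)) >= center_sep) break
    }
    labels <- rep(seq_len(n_clusters), each = n_per_cluster)
    noise <- matrix(stats::rnorm(length(labels) * dims, sd = sigma),
                    length(labels), dims)
    list(points = centers[labels, , drop = FALSE] + noise,
         labels = labels, centers = centers)
  })
}

#' Write a synthetic network and its block labels to disk
#'
#' Emits the same edge-list format [read_edge_list()] consumes, plus a
#' sidecar TSV of true lncRNA block labels, so command-line runs and tests
#' can share fixtures. The generating seed is echoed in a header comment.
#'
#' @param spec a [block_network_spec()].
#' @param edge_path output edge-list path.
#' @param labels_path output path for the lncRNA block labels (TSV with
#'   columns `lncrna`, `block`); `NULL` skips it.
#' @return The generated list from [generate_block_network()], invisibly.
#' @export
write_block_network <- function(spec, edge_path, labels_path = NULL) {
  sim <- generate_block_network(spec)
  write_edge_list(sim$network, edge_path)
  hdr <- sprintf("#seed: %d", spec$seed)
  lines <- readLines(edge_path)
  writeLines(c(lines[1:2], hdr, lines[-(1:2)]), edge_path)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(lncrna = sim$network$lncrna_ids, block = sim$lncrna_blocks),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(sim)
}
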