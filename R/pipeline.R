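#' ACCBN interaction scores
#'
#' The full prediction pipeline on one training network:
#' 1. extract the association profiles (adjacency rows for lncRNAs, columns
#'    for proteins);
#' 2. cluster them with the ant colony ([run_clustering()]);
#' 3. build the linear neighborhood similarity matrix ([lns_weights()]);
#' 4. enhance it with the recovered clusters ([enhance_with_clusters()]);
#' 5. propagate the known labels over the enhanced similarity graph
#'    ([propagate()]).
#'
#' Both similarities the method computes are used by default: the lncRNA
#' side propagates each protein's labels over the lncRNA similarity graph,
#' the protein side propagates each lncRNA's labels over the protein
#' similarity graph, and the final score is their average. `side` restricts
#' the pipeline to a single pass.
#'
#' @param net training [interaction_network()].
#' @param ant an [ant_params()] object (clustering settings, incl. seed; the
#'   protein-side clustering derives its seed from it).
#' @param lns an [lns_params()] object.
#' @param prop a [propagation_params()] object.
#' @param gamma weight of the uniform within-cluster kernel (see
#'   [enhance_with_clusters()]).
#' @param delta cross-cluster similarity retention.
#' @param side `"both"` (default), `"lncrna"` or `"protein"`.
#' @return n x m score matrix; higher scores mean more plausible
#'   interactions. Attribute `n_clusters` reports the cluster counts used
#'   (one per side run).
#' @examples
#' sim <- generate_block_network(block_network_spec(
#'   n_lncrna = 30, n_protein = 15, n_blocks = 3, seed = 3))
#' P <- accbn_scores(sim$network)
#' rank_predictions(P, sim$network)[1:5, ]
#' @export
accbn_scores <- function(net, ant = ant_params(), lns = lns_params(),
                         prop = propagation_params(), gamma = 0.5,
                         delta = 1.0, side = c("both", "lncrna", "protein")) {
  stopifnot(inherits(net, "interaction_network"))
  side <- match.arg(side)
  n_clusters <- integer()
  one_side <- function(profiles, M, seed_offset) {
    ant_side <- ant
    ant_side$seed <- (ant$seed + seed_offset) %% 2147483647L
    clusters <- run_clustering(profiles, ant_side)
    n_clusters[[length(n_clusters) + 1L]] <<- nrow(clusters$centers)
    W <- lns_weights(profiles, lns)
    W <- enhance_with_clusters(W, clusters$assignments, gamma, delta)
    propagate(W, M, prop)
  }
  P <- switch(side,
    lncrna = one_side(lncrna_profiles(net), net$adjacency, 0L),
    protein = t(one_side(protein_profiles(net), t(net$adjacency), 1L)),
    both = {
      Pl <- one_side(lncrna_profiles(net), net$adjacency, 0L)
      Pp <- t(one_side(protein_profiles(net), t(net$adjacency), 1L))
      (Pl + Pp) / 2
    }
  )
  P <- structure(as.matrix(P), dimnames = dimnames(net$adjacency))
  attr(P, "n_clusters") <- n_clusters
  P
}

#' Sweep the propagation absorption probability
#'
#' Cross-validates the ACCBN pipeline over a grid of `rho_prop` values.
#' Clustering and similarity construction do not depend on `rho_prop`, so
#' per fold they are computed once and only the propagation step is redone
#' for each grid value — the sweep costs little more than a single CV run.
#'
#' @param net an [interaction_network()].
#' @param rhos numeric grid of absorption probabilities in `[0, 1)`.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @param method_config settings list as in [predict_scores()] (the `prop`
#'   entry's `rho_prop` is overridden by the grid).
#' @param max_negatives optional negative subsample size per fold.
#' @return Data frame with one row per rho: `rho`, mean `accuracy`, mean
#'   `auc` over all repeat x fold cells.
#' @export
rho_sweep <- function(net, rhos = seq(0.1, 0.9, by = 0.1), k = 5,
                      repeats = 1, seed = 1L, method_config = list(),
                      max_negatives = NULL) {
  stopifnot(all(rhos >= 0), all(rhos < 1))
  seed <- as.integer(seed)
  acc <- auc <- matrix(0, repeats * k, length(rhos))
  ri <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- kfold_edge_splits(net, k, seed = seed + 7919L * rep_i)
    for (f in seq_len(k)) {
      test_edges <- folds[[f]]
      train <- mask_edges(net, test_edges)
      fold_seed <- (seed + 7919L * rep_i + 101L * f) %% 2147483647L
      gamma <- method_config$gamma %||% 0.5
      delta <- method_config$delta %||% 1.0
      lnsp <- do.call(lns_params, method_config$lns %||% list())
      side_W <- function(profiles, seed_offset) {
        ant_args <- utils::modifyList(
          list(seed = (fold_seed + seed_offset) %% 2147483647L),
          method_config$ant %||% list()
        )
        clusters <- run_clustering(profiles, do.call(ant_params, ant_args))
        enhance_with_clusters(lns_weights(profiles, lnsp),
                              clusters$assignments, gamma, delta)
      }
      Wl <- side_W(lncrna_profiles(train), 0L)
      Wp <- side_W(protein_profiles(train), 1L)
      ev <- fold_eval_pairs(net, test_edges, max_negatives,
                            neg_seed = fold_seed)
      ri <- ri + 1L
      for (g in seq_along(rhos)) {
        pp <- propagation_params(rho_prop = rhos[g])
        P <- (propagate(Wl, train$adjacency, pp) +
                t(propagate(Wp, t(train$adjacency), pp))) / 2
        s <- P[ev$index]
        y <- ev$labels
        thr <- sort(s, decreasing = TRUE)[sum(y == 1)]
        met <- basic_metrics(confusion_at_threshold(s, y, thr))
        acc[ri, g] <- met$accuracy
        auc[ri, g] <- auc_score(s, y)
      }
    }
  }
  data.frame(rho = rhos,
             accuracy = colMeans(acc),
             auc = colMeans(auc))
}
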