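#' Split positive edges into k cross-validation folds
#'
#' Randomly partitions the known (positive) interactions into `k` disjoint
#' folds whose sizes differ by at most one. In edge-masking cross-validation
#' each fold in turn is hidden from the predictor and used as the test set.
#'
#' @param net an [interaction_network()].
#' @param k number of folds.
#' @param seed optional integer; when non-`NULL` the fold assignment is
#'   drawn from a generator seeded locally with it (the caller's RNG state
#'   is untouched), making the split reproducible.
#' @return A list of `k` two-column integer matrices (`row` = lncRNA index,
#'   `col` = protein index).
#' @export
kfold_edge_splits <- function(net, k, seed = NULL) {
  stopifnot(inherits(net, "interaction_network"), k >= 1)
  pos <- which(net$adjacency == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < k) {
    stop("cannot make ", k, " folds from ", n_pos, " positive edges")
  }
  perm <- if (is.null(seed)) {
    sample.int(n_pos)
  } else {
    withr::with_seed(seed, sample.int(n_pos))
  }
  fold_id <- rep_len(seq_len(k), n_pos)[order(perm)]
  lapply(seq_len(k), function(f) {
    unname(pos[fold_id == f, , drop = FALSE])
  })
}

#' Mask test edges out of a network
#'
#' Returns a copy of the network with the given positive edges set to 0
#' (the original is untouched). Masking a pair that is not a known edge is
#' an error — it would silently corrupt the evaluation.
#'
#' @param net an [interaction_network()].
#' @param test_edges two-column matrix of (lncRNA index, protein index)
#'   pairs, as produced by [kfold_edge_splits()].
#' @return A new [interaction_network()] with those entries zeroed.
#' @export
mask_edges <- function(net, test_edges) {
  stopifnot(inherits(net, "interaction_network"))
  test_edges <- matrix(as.integer(test_edges), ncol = 2)
  adj <- net$adjacency
  if (nrow(test_edges) > 0) {
    if (any(adj[test_edges] != 1)) {
      stop("cannot mask a pair that is not a known edge")
    }
    adj[test_edges] <- 0
  }
  interaction_network(adj, net$lncrna_ids, net$protein_ids)
}

#' Confusion counts at a score threshold
#'
#' A pair is predicted interacting iff its score is at least `threshold`.
#'
#' @param scores numeric score vector over the evaluated pairs.
#' @param labels binary truth vector (1 = interacting) of the same length.
#' @param threshold decision threshold.
#' @return A list of class `confusion_counts` with integer fields `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  pred <- scores >= threshold
  structure(list(
    tp = sum(pred & labels == 1),
    tn = sum(!pred & labels == 0),
    fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1)
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Threshold classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)`, `sensitivity = recall = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)` and
#' `F1 = 2 * precision * recall / (precision + recall)`. A ratio with a zero
#' denominator is reported as 0 and the metric name is recorded in the
#' `undefined` attribute instead of raising, so degenerate folds do not
#' abort a long cross-validation.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return Named list with `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1`, plus an `undefined` character attribute naming any
#'   zero-denominator metrics.
#' @export
basic_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  undefined <- character()
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (tp + fn == 0) undefined <- c(undefined, "sensitivity")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  if (precision + sensitivity == 0) undefined <- unique(c(undefined, "f1"))
  out <- list(
    sensitivity = sensitivity,
    specificity = safe_ratio(tn, tn + fp),
    precision = precision,
    accuracy = (tp + tn) / total,
    f1 = safe_ratio(2 * precision * sensitivity, precision + sensitivity)
  )
  attr(out, "undefined") <- undefined
  out
}

#' Area under the ROC curve
#'
#' The probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, with ties counted 1/2 (midrank convention). Computed from
#' the rank-sum identity, so it is exact and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric score vector.
#' @param labels binary truth vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("auc_score needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Area of the precision-recall step curve traversed in descending score
#' order. Tied scores are processed as one block (precision evaluated at the
#' block end), so the result does not depend on the input order of tied
#' pairs.
#'
#' @param scores numeric score vector.
#' @param labels binary truth vector with at least one positive.
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("aupr_score needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y)
  ranks <- seq_along(y)
  block_end <- ranks[!duplicated(s, fromLast = TRUE)]  # last index per tie block
  recall <- cum_tp[block_end] / n_pos
  precision <- cum_tp[block_end] / block_end
  sum(diff(c(0, recall)) * precision)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same points;
#' 1 means identical partitions (up to relabeling), ~0 means chance-level
#' agreement. Used to validate cluster recovery on data with known labels.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Score a network with one of the implemented predictors
#'
#' Dispatcher used by the cross-validation harness and the command-line
#' interface.
#'
#' @param net training [interaction_network()].
#' @param method `"accbn"` (ant-colony clustering + enhanced LNS + label
#'   propagation), `"rwr"` (random walk with restart) or `"lpbni"`
#'   (two-phase resource allocation).
#' @param config named list of method settings; recognised entries are
#'   `ant` ([ant_params()] arguments), `lns` ([lns_params()] arguments),
#'   `prop` ([propagation_params()] arguments), `gamma`, `delta` (similarity
#'   enhancement) and `rwr` ([baseline_params()] arguments).
#' @param seed integer seed for the method's stochastic parts (ant colony);
#'   an explicit `config$ant$seed` wins over it.
#' @return n x m score matrix.
#' @export
predict_scores <- function(net, method = c("accbn", "rwr", "lpbni"),
                           config = list(), seed = 1L) {
  method <- match.arg(method)
  switch(method,
    accbn = {
      ant_args <- utils::modifyList(list(seed = seed),
                                    config$ant %||% list())
      accbn_scores(
        net,
        ant = do.call(ant_params, ant_args),
        lns = do.call(lns_params, config$lns %||% list()),
        prop = do.call(propagation_params, config$prop %||% list()),
        gamma = config$gamma %||% 0.5,
        delta = config$delta %||% 1.0,
        side = config$side %||% "both"
      )
    },
    rwr = rwr_scores(net, do.call(baseline_params, config$rwr %||% list())),
    lpbni = lpbni_scores(net)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Collect the evaluated pairs for one fold: the masked test positives plus
# the negative universe (every pair with no known interaction in the FULL
# network). Returns linear indices into the adjacency plus labels.
fold_eval_pairs <- function(net, test_edges, max_negatives = NULL,
                            neg_seed = NULL) {
  n <- nrow(net$adjacency)
  neg_idx <- which(net$adjacency == 0)
  if (!is.null(max_negatives) && max_negatives < length(neg_idx)) {
    pick <- withr::with_seed(neg_seed %||% 0L,
                             sample.int(length(neg_idx), max_negatives))
    neg_idx <- neg_idx[pick]
  }
  test_lin <- (test_edges[, 2] - 1L) * n + test_edges[, 1]
  list(index = c(test_lin, neg_idx),
       labels = c(rep(1, length(test_lin)), rep(0, length(neg_idx))))
}

#' Repeated k-fold edge-masking cross-validation
#'
#' The known interactions are split into `k` folds; for every repeat and
#' fold the test edges are masked out of the training network, the chosen
#' predictor is fit on the masked network alone (for ACCBN this re-runs
#' clustering and LNS, so no information from the masked edges leaks in),
#' and the resulting scores are evaluated over the test positives plus all
#' never-interacting pairs. Seven metrics are recorded per fold: AUC, AUPR,
#' sensitivity, specificity, precision, accuracy and F1. The evaluation
#' protocol of the source experiments is `k = 5`, `repeats = 20`.
#'
#' Binary metrics need an operating point: by default the threshold for each
#' fold is the score of the R-th ranked evaluated pair, where R is the
#' number of test positives (a prevalence-matched, parameter-free choice);
#' pass `threshold` to override.
#'
#' @param net an [interaction_network()].
#' @param method predictor name, see [predict_scores()].
#' @param k number of folds (default 5).
#' @param repeats number of independent k-fold repetitions (default 20).
#' @param seed integer seed; the whole report is reproducible from it.
#' @param method_config settings list passed to [predict_scores()].
#' @param threshold fixed decision threshold, or `NULL` for the top-R rule.
#' @param max_negatives optional cap on the number of sampled negatives per
#'   fold (for very large networks); `NULL` evaluates all negatives.
#' @return An object of class `cv_report`: list with `per_fold` (data frame
#'   of one row per repeat x fold), `summary` (mean and sd per metric) and
#'   `config` (echo of the call).
#' @examples
#' net <- generate_block_network(block_network_spec(
#'   n_lncrna = 30, n_protein = 15, n_blocks = 3, seed = 7))$network
#' run_cv(net, "lpbni", k = 5, repeats = 1, seed = 7)
#' @export
run_cv <- function(net, method = c("accbn", "rwr", "lpbni"), k = 5,
                   repeats = 20, seed = 1L, method_config = list(),
                   threshold = NULL, max_negatives = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(net, "interaction_network"), repeats >= 1)
  seed <- as.integer(seed)
  rows <- vector("list", repeats * k)
  ri <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- kfold_edge_splits(net, k, seed = seed + 7919L * rep_i)
    for (f in seq_len(k)) {
      test_edges <- folds[[f]]
      train <- mask_edges(net, test_edges)
      stopifnot(all(train$adjacency[test_edges] == 0))  # no leakage
      fold_seed <- (seed + 7919L * rep_i + 101L * f) %% 2147483647L
      scores <- predict_scores(train, method, method_config,
                               seed = fold_seed)
      ev <- fold_eval_pairs(net, test_edges, max_negatives,
                            neg_seed = fold_seed)
      s <- scores[ev$index]
      y <- ev$labels
      thr <- if (is.null(threshold)) {
        sort(s, decreasing = TRUE)[sum(y == 1)]
      } else {
        threshold
      }
      met <- basic_metrics(confusion_at_threshold(s, y, thr))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        repeat_id = rep_i, fold = f,
        auc = auc_score(s, y), aupr = aupr_score(s, y),
        sensitivity = met$sensitivity, specificity = met$specificity,
        precision = met$precision, accuracy = met$accuracy, f1 = met$f1
      )
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("repeat_id", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(per_fold[metric_cols], mean, numeric(1)),
    sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
    row.names = NULL
  )
  structure(list(
    per_fold = per_fold,
    summary = summary,
    config = list(method = method, k = k, repeats = repeats, seed = seed,
                  threshold = threshold, max_negatives = max_negatives,
                  method_config = method_config)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", x$config$method, "-", x$config$repeats, "x",
      x$config$k, "-fold CV (seed", paste0(x$config$seed, ")\n"))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialise a cross-validation report
#'
#' Writes the report as JSON (summary + config + per-fold rows) and/or as a
#' flat CSV of per-fold rows.
#'
#' @param report a `cv_report`.
#' @param json_path,csv_path output paths; `NULL` skips that format.
#' @return `report`, invisibly.
#' @export
write_cv_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(config = report$config, summary = report$summary,
           per_fold = report$per_fold),
      json_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_fold, csv_path, row.names = FALSE)
  }
  invisible(report)
}
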