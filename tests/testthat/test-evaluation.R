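test_that("folds partition the positive edges into near-equal parts", {
  net <- random_net(10, 8, 0.3, seed = 2)
  n_pos <- sum(net$adjacency)
  folds <- kfold_edge_splits(net, 5, seed = 7)
  sizes <- vapply(folds, nrow, 0L)
  expect_equal(sum(sizes), n_pos)
  expect_lte(diff(range(sizes)), 1)
  all_edges <- do.call(rbind, folds)
  expect_equal(nrow(unique(all_edges)), n_pos)      # pairwise disjoint
  expect_true(all(net$adjacency[all_edges] == 1))
  folds2 <- kfold_edge_splits(net, 5, seed = 7)
  expect_identical(folds, folds2)
  tiny <- interaction_network(matrix(c(1, 0, 1, 0), 2, 2))
  expect_error(kfold_edge_splits(tiny, 5), "folds")
})

test_that("masking removes exactly the requested edges and rejects non-edges", {
  net <- random_net(8, 6, 0.4, seed = 3)
  pos <- which(net$adjacency == 1, arr.ind = TRUE)
  all_masked <- mask_edges(net, pos)
  expect_true(all(all_masked$adjacency == 0))
  expect_network_equal(mask_edges(net, pos[0, , drop = FALSE]), net)
  some <- pos[1:5, ]
  masked <- mask_edges(net, some)
  expect_equal(sum(masked$adjacency), sum(net$adjacency) - 5)
  non_edge <- which(net$adjacency == 0, arr.ind = TRUE)[1, , drop = FALSE]
  expect_error(mask_edges(net, non_edge), "not a known edge")
})

test_that("confusion counts follow the threshold rule exactly", {
  withr::local_seed(5)
  s <- runif(20); y <- rbinom(20, 1, 0.4)
  c_lo <- confusion_at_threshold(s, y, min(s))
  expect_equal(c_lo$fn, 0); expect_equal(c_lo$tn, 0)
  c_hi <- confusion_at_threshold(s, y, max(s) + 1)
  expect_equal(c_hi$tp, 0); expect_equal(c_hi$fp, 0)
  thr <- 0.5
  cc <- confusion_at_threshold(s, y, thr)
  # per-pair loop oracle
  tp <- tn <- fp <- fn <- 0
  for (i in 1:20) {
    if (s[i] >= thr && y[i] == 1) tp <- tp + 1
    if (s[i] >= thr && y[i] == 0) fp <- fp + 1
    if (s[i] < thr && y[i] == 1) fn <- fn + 1
    if (s[i] < thr && y[i] == 0) tn <- tn + 1
  }
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = tp, tn = tn, fp = fp, fn = fn))
})

test_that("threshold metrics match their defining formulas", {
  m <- basic_metrics(list(tp = 3, tn = 90, fp = 5, fn = 2))
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$precision, 0.375)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 90 / 95)
  expect_equal(m$f1, 2 * (0.375 * 0.6) / (0.375 + 0.6))

  perfect <- basic_metrics(list(tp = 4, tn = 4, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))

  # harmonic-mean identity: precision == recall == r implies F1 == r
  pr <- basic_metrics(list(tp = 6, tn = 10, fp = 2, fn = 2))
  expect_equal(pr$precision, pr$sensitivity)
  expect_equal(pr$f1, pr$precision)

  degenerate <- basic_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_equal(degenerate$precision, 0)
  expect_true("precision" %in% attr(degenerate, "undefined"))
})

test_that("AUC equals the exhaustive pair-counting probability with midrank ties", {
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
  withr::local_seed(9)
  for (rep in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # forces ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_score(s, y), mean(pairs), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(auc_score(exp(3 * s), y), auc_score(s, y), tolerance = 1e-12)
  }
})

test_that("AUPR follows the descending-order step curve", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # single positive ranked last among z items: area = 1/z
  z <- 7
  s <- seq(1, 0, length.out = z)
  y <- c(rep(0, z - 1), 1)
  expect_equal(aupr_score(s, y), 1 / z)
  expect_error(aupr_score(1:3, c(0, 0, 0)), "positive")
  withr::local_seed(10)
  s <- runif(25); y <- rbinom(25, 1, 0.3); y[1] <- 1
  # rank-by-rank cumulative oracle (distinct scores, no tie blocks)
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  tp <- cumsum(ys)
  prec <- tp / seq_along(ys)
  rec <- tp / sum(ys)
  oracle <- sum(diff(c(0, rec)) * prec)
  expect_equal(aupr_score(s, y), oracle, tolerance = 1e-12)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  withr::local_seed(12)
  for (rep in 1:10) {
    a <- sample(4, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("AUC agrees with the pROC reference on a random instance", {
  skip_if_not_installed("pROC")
  withr::local_seed(14)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("cross-validation bookkeeping: fold counts, determinism, schema", {
  net <- interaction_network(
    matrix(c(1, 1, 0, 0,
             0, 1, 1, 0,
             0, 0, 1, 1), 3, 4, byrow = TRUE),
    paste0("L", 1:3), paste0("P", 1:4)
  )
  rep1 <- suppressWarnings(run_cv(net, "lpbni", k = 2, repeats = 1, seed = 3))
  expect_equal(nrow(rep1$per_fold), 2)
  expect_setequal(
    rep1$summary$metric,
    c("auc", "aupr", "sensitivity", "specificity", "precision",
      "accuracy", "f1")
  )
  expect_true(all(rep1$per_fold[, -(1:2)] >= 0 &
                  rep1$per_fold[, -(1:2)] <= 1))
  rep2 <- suppressWarnings(run_cv(net, "lpbni", k = 2, repeats = 1, seed = 3))
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_error(run_cv(net, "nope"), "arg")
})

test_that("summary means equal recomputation from the per-fold rows", {
  net <- random_net(12, 8, 0.3, seed = 4)
  rep <- suppressWarnings(run_cv(net, "rwr", k = 3, repeats = 2, seed = 1))
  expect_equal(nrow(rep$per_fold), 6)
  for (metric in rep$summary$metric) {
    expect_equal(rep$summary$mean[rep$summary$metric == metric],
                 mean(rep$per_fold[[metric]]))
  }
  f <- withr::local_tempfile(fileext = ".json")
  g <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(rep, f, g)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(js$per_fold), 6)
  expect_equal(js$summary$mean, rep$summary$mean, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(g)), 6)
})
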