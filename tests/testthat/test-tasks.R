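toy_embedding <- function(ids, mat) {
  rownames(mat) <- ids
  structure(mat, class = c("embedding_matrix", class(mat)), method = "toy", seed = 0)
}

test_that("edge features concatenate endpoints in canonical order", {
  emb <- toy_embedding(c("a", "b"), matrix(c(1, 3, 2, 4), 2)) # a=[1,2], b=[3,4]
  # supplied orientation (b, a): still canonical (a first, smaller index)
  X <- edge_features(emb, data.frame(source = "b", target = "a"))
  expect_equal(unname(X[1, ]), c(1, 2, 3, 4))
  X2 <- edge_features(emb, data.frame(source = "a", target = "b"))
  expect_equal(X, X2)
  expect_equal(ncol(X), 2 * ncol(emb))
  expect_error(
    edge_features(emb, data.frame(source = "a", target = "zz")),
    "edge 1"
  )
})

test_that("classifier fitting is deterministic and handles degenerate inputs", {
  set.seed(2)
  X <- cbind(x1 = c(rnorm(50, -2), rnorm(50, 2)), x2 = rnorm(100))
  y <- rep(c("n", "p"), each = 50)
  spec <- classifier_spec("decision_tree", grid = data.frame(max_depth = 5, min_leaf = 1))
  fit <- fit_classifier(X, y, spec)
  expect_equal(as.character(predict_classes(fit, X)), y) # separable: 100% train

  # constant features -> majority class everywhere
  Xc <- matrix(1, 90, 2)
  yc <- rep(c("n", "p"), c(60, 30))
  fitc <- fit_classifier(Xc, yc, spec)
  expect_true(all(predict_classes(fitc, Xc) == "n"))

  expect_error(fit_classifier(X, rep("p", 100), spec), "2 classes")

  rf <- classifier_spec("random_forest", grid = data.frame(trees = 100, max_depth = 5, min_leaf = 1), seed = 9)
  f1 <- predict_classes(fit_classifier(X, y, rf), X)
  f2 <- predict_classes(fit_classifier(X, y, rf), X)
  expect_identical(f1, f2)
})

test_that("grid search selects by inner-CV balanced accuracy with first-entry ties", {
  set.seed(4)
  X <- cbind(rnorm(120), rnorm(120))
  y <- rep(c("a", "b"), 60)
  grid <- data.frame(max_depth = c(3, 3), min_leaf = c(2, 2)) # identical rows tie
  fit <- fit_classifier(X, y, classifier_spec("decision_tree", grid = grid, seed = 5))
  expect_equal(nrow(fit$cv_results), 2)
  expect_equal(unname(unlist(fit$best_params)), unname(unlist(grid[1, ])))
})

test_that("node-type prediction is perfect on a linearly separated toy embedding", {
  ids <- sprintf("n%02d", 1:40)
  g <- knowledge_graph(
    data.frame(node_id = ids, node_type = rep(c("A", "B"), each = 20)),
    data.frame(source = ids[1], target = ids[21], edge_type = "t")
  )
  emb <- toy_embedding(ids, cbind(rep(c(-1, 1), each = 20) + rnorm(40, sd = 0.01), rnorm(40, sd = 0.01)))
  res <- run_node_type_prediction(
    g, emb, 2,
    classifier_spec("decision_tree", grid = data.frame(max_depth = 3, min_leaf = 1)),
    n_holdouts = 3, seed = 1
  )
  expect_equal(tidy(res)$balanced_accuracy, rep(1, 3))
})

test_that("shuffled labels drive balanced accuracy to chance level 1/k", {
  k <- 5
  ids <- sprintf("n%03d", 1:500)
  set.seed(6)
  g <- knowledge_graph(
    data.frame(node_id = ids, node_type = sample(rep(LETTERS[1:k], 100))),
    data.frame(source = ids[1], target = ids[2], edge_type = "t")
  )
  emb <- toy_embedding(ids, matrix(rnorm(1000), 500, 2)) # uninformative features
  res <- run_node_type_prediction(
    g, emb, k,
    classifier_spec("decision_tree", grid = data.frame(max_depth = 4, min_leaf = 5)),
    n_holdouts = 5, seed = 2
  )
  ba <- mean(tidy(res)$balanced_accuracy)
  # null calibration: around 1/k with generous stochastic tolerance
  expect_lt(abs(ba - 1 / k), 0.08)
})

test_that("task results recompute their own summaries", {
  gen <- generate_kg(dense_target_spec(2))
  res <- run_specific_edge_prediction(
    gen$graph, "A-B", line_params(dim = 8, seed = 1),
    classifier_spec("decision_tree", grid = data.frame(max_depth = 8, min_leaf = 5)),
    n_holdouts = 2, seed = 4
  )
  tr <- tidy(res)
  expect_equal(nrow(tr), 2)
  s <- res$summary
  expect_equal(
    s$mean[s$metric == "balanced_accuracy"],
    mean(tr$balanced_accuracy)
  )
  expect_equal(
    s$sd[s$metric == "balanced_accuracy"],
    stats::sd(tr$balanced_accuracy)
  )
  g1 <- glance(res)
  expect_equal(g1$balanced_accuracy_mean, mean(tr$balanced_accuracy))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("generic-edge prediction learns clique structure and nulls out on noise", {
  a <- sprintf("a%02d", 1:20)
  b <- sprintf("b%02d", 1:20)
  g <- kg_from_pairs(rbind(clique_pairs(a), clique_pairs(b), cbind("a01", "b01")))
  res <- run_generic_edge_prediction(
    g, node2vec_params(dim = 10, walks_per_node = 5, walk_length = 30, epochs = 5),
    classifier_spec("random_forest", grid = data.frame(trees = 100, max_depth = NA, min_leaf = 1)),
    n_holdouts = 3, seed = 2
  )
  expect_gte(glance(res)$balanced_accuracy_mean, 0.9)

  # permuted predictions are chance: balanced accuracy ~ 0.5
  yte <- factor(rep(c("negative", "positive"), each = 600))
  set.seed(3)
  perm <- sample(yte)
  ba <- balanced_accuracy(confusion_table(yte, perm))
  expect_lt(abs(ba - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("unbiased specific-edge runs always report FN 0 and beat the biased run on positives", {
  gen <- generate_kg(dense_target_spec(11))
  g <- gen$graph
  dt <- classifier_spec("decision_tree", grid = data.frame(max_depth = 10, min_leaf = 5))
  ru <- run_specific_edge_prediction(g, "A-B", line_params(dim = 10, seed = 3), dt,
    n_holdouts = 2, seed = 5, unbiased = TRUE
  )
  rb <- run_specific_edge_prediction(g, "A-B", line_params(dim = 10, seed = 3), dt,
    n_holdouts = 2, seed = 5, unbiased = FALSE
  )
  expect_equal(tidy(ru)$fn_pct, rep(0, 2))
  expect_true(all(tidy(rb)$fn_pct > 0))
  expect_gt(
    glance(ru)$accuracy_positive_mean,
    glance(rb)$accuracy_positive_mean - 0.1 # direction with per-run noise slack
  )
})
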