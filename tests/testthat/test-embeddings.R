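test_that("transition distributions reproduce the walk-bias rule on known cases", {
  pg <- path_graph(c("a", "b", "c"))
  # balanced: uniform over neighbours
  tp <- transition_distribution(pg, "b", "a", node2vec_preset("balanced"))
  expect_equal(tp$probability, c(0.5, 0.5))
  # bfs on a path: return 5, distance-2 gets explore weight 0.2
  tp <- transition_distribution(pg, "b", "a", node2vec_preset("bfs"))
  expect_equal(tp$probability[tp$node_id == "a"], 5 / 5.2, tolerance = 1e-12)
  expect_equal(tp$probability[tp$node_id == "c"], 0.2 / 5.2, tolerance = 1e-12)
  # dfs on a triangle: c is adjacent to prev -> weight 1
  tri <- kg_from_pairs(cbind(c("a", "b", "c"), c("b", "c", "a")))
  tp <- transition_distribution(tri, "b", "a", node2vec_preset("dfs"))
  expect_equal(tp$probability[tp$node_id == "a"], 0.2 / 1.2, tolerance = 1e-12)
  expect_equal(tp$probability[tp$node_id == "c"], 1 / 1.2, tolerance = 1e-12)
  # first step: uniform
  tp <- transition_distribution(pg, "b", NULL, node2vec_preset("bfs"))
  expect_equal(tp$probability, c(0.5, 0.5))
  expect_error(
    transition_distribution(kg_from_pairs(cbind("a", "b")), "a", "b", node2vec_params()),
    NA
  )
})

test_that("transition distributions match brute-force enumeration on random graphs", {
  params_pool <- list(
    node2vec_preset("bfs"), node2vec_preset("dfs"), node2vec_preset("balanced"),
    node2vec_params(return_weight = 2.5, explore_weight = 0.7)
  )
  cases <- 0
  set.seed(99)
  while (cases < 50) {
    g <- er_graph(sample(10:40, 1), 0.2, seed = sample.int(1e6, 1))
    ed <- kg_edges(g)
    if (nrow(ed) == 0) next
    e <- ed[sample.int(nrow(ed), 1), ]
    prev <- e$source
    curr <- e$target
    p <- params_pool[[(cases %% length(params_pool)) + 1]]
    got <- transition_distribution(g, curr, prev, p)
    want <- oracle_transition(g, prev, curr, p$return_weight, p$explore_weight)
    expect_equal(sum(got$probability), 1, tolerance = 1e-12)
    expect_equal(
      stats::setNames(got$probability, got$node_id)[names(want)],
      want,
      tolerance = 1e-12
    )
    cases <- cases + 1
  }
})

test_that("walk corpora are edge-consistent, complete and seed-deterministic", {
  # a single edge forces strict alternation
  g1 <- kg_from_pairs(cbind("a", "b"))
  w <- generate_walks(g1, node2vec_params(walks_per_node = 3, walk_length = 4))
  expect_true(all(apply(w, 1, function(r) all(r[-1] != r[-length(r)]))))

  g <- er_graph(40, 0.12, seed = 5)
  deg <- node_degrees(g)$degree
  p <- node2vec_params(walks_per_node = 4, walk_length = 12, seed = 8)
  w <- generate_walks(g, p)
  expect_equal(nrow(w), 4 * sum(deg > 0))
  keys <- kglink:::kg_pair_keys(g)
  n <- kg_n_nodes(g)
  for (i in seq_len(nrow(w))) {
    a <- w[i, -ncol(w)]
    b <- w[i, -1]
    expect_true(all(kglink:::pair_key(pmin(a, b), pmax(a, b), n) %in% keys))
  }
  w2 <- generate_walks(g, p)
  expect_identical(unclass(w), unclass(w2))
})

test_that("empirical next-step frequencies match the transition distribution", {
  g <- er_graph(10, 0.5, seed = 31)
  p <- node2vec_preset("bfs", walks_per_node = 400, walk_length = 40, seed = 17)
  w <- generate_walks(g, p)
  # pick the most frequent (prev, curr) context in the corpus
  prev <- as.vector(w[, 1:(ncol(w) - 2)])
  curr <- as.vector(w[, 2:(ncol(w) - 1)])
  nxt <- as.vector(w[, 3:ncol(w)])
  ctx <- paste(prev, curr)
  top <- names(sort(table(ctx), decreasing = TRUE))[1]
  sel <- ctx == top
  pc <- as.integer(strsplit(top, " ")[[1]])
  ids <- kg_nodes(g)$node_id
  want <- transition_distribution(g, ids[pc[2]], ids[pc[1]], p)
  tab <- table(factor(ids[nxt[sel]], levels = want$node_id))
  nobs <- sum(tab)
  for (i in seq_along(want$node_id)) {
    pr <- want$probability[i]
    expect_lte(abs(tab[[i]] - nobs * pr), 3 * sqrt(nobs * pr * (1 - pr)) + 1)
  }
})

test_that("skip-gram separates disconnected cliques and is reproducible", {
  g <- two_cliques_graph(10)
  p <- node2vec_params(dim = 10, walks_per_node = 5, walk_length = 30, epochs = 5, seed = 3)
  emb <- embed_graph(g, p)
  expect_equal(nrow(emb), 20)
  expect_true(all(is.finite(emb)))
  expect_gt(clique_separation(emb), 0)

  emb2 <- embed_graph(g, p)
  expect_identical(as.matrix(emb), as.matrix(emb2))

  loss <- attr(emb, "loss")
  expect_lt(loss[length(loss)], loss[1]) # decreasing trend over epochs
})

test_that("skip-gram separates barbell clique centroids beyond internal dispersion", {
  a <- sprintf("a%02d", 1:8)
  b <- sprintf("b%02d", 1:8)
  g <- kg_from_pairs(rbind(clique_pairs(a), clique_pairs(b), cbind("a01", "b01")))
  emb <- embed_graph(g, node2vec_params(
    dim = 10, walks_per_node = 8, walk_length = 40, epochs = 5, seed = 7
  ))
  m <- as.matrix(emb)
  ia <- match(a, rownames(m))
  ib <- match(b, rownames(m))
  ca <- colMeans(m[ia, ])
  cb <- colMeans(m[ib, ])
  gap <- sqrt(sum((ca - cb)^2))
  disp_a <- mean(sqrt(rowSums(sweep(m[ia, ], 2, ca)^2)))
  disp_b <- mean(sqrt(rowSums(sweep(m[ib, ], 2, cb)^2)))
  expect_gt(gap, max(disp_a, disp_b))
})

test_that("LINE order-1 separates cliques; order-2 pairs shared-context hubs", {
  g <- two_cliques_graph(10)
  le <- train_line(g, line_params(dim = 10, order = 1, seed = 4))
  expect_gt(clique_separation(le), 0)
  le2 <- train_line(g, line_params(dim = 10, order = 1, seed = 4))
  expect_identical(as.matrix(le), as.matrix(le2))

  # two hubs sharing every leaf: identical neighbourhoods, no direct edge
  leaves <- sprintf("l%02d", 1:12)
  g2 <- kg_from_pairs(rbind(cbind("hub1", leaves), cbind("hub2", leaves)))
  e2 <- train_line(g2, line_params(dim = 8, order = 2, total_samples = 5e4, seed = 5))
  cs <- cosine_matrix(e2)
  h1 <- match("hub1", rownames(e2))
  h2 <- match("hub2", rownames(e2))
  sims <- cs[h1, -h1]
  expect_equal(names(which.max(sims)), "hub2")

  edgeless <- knowledge_graph(
    data.frame(node_id = c("a", "b"), node_type = "x"),
    data.frame(source = character(), target = character(), edge_type = character())
  )
  expect_error(train_line(edgeless, line_params()), "no edges")
  expect_error(generate_walks(edgeless, node2vec_params()), "no edges")
})

test_that("the 2D projection honours its contract", {
  set.seed(1)
  X <- matrix(rnorm(200), 40, 5)
  Y <- project_2d(X, seed = 2)
  expect_equal(dim(Y), c(40, 2))
  expect_true(all(is.finite(Y)))
  # degenerate: identical rows still produce finite coordinates
  Yd <- project_2d(matrix(1, 10, 4), seed = 1)
  expect_true(all(is.finite(Yd)))
  expect_error(project_2d(matrix(1, 2, 4)), "at least 3 rows")
})
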