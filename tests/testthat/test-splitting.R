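test_that("connected holdout honours the spanning-forest constraint", {
  tri <- kg_from_pairs(cbind(c("a", "b", "c"), c("b", "c", "a")))
  sp <- connected_holdout(tri, 1 / 3, seed = 1)
  expect_equal(nrow(sp$test_pairs), 1)
  expect_equal(kg_n_components(training_graph(tri, sp)), 1)

  # a tree has only bridges: empty test set plus a warning
  pg <- path_graph(c("a", "b", "c"))
  expect_warning(sp <- connected_holdout(pg, 0.3, seed = 2), "forest")
  expect_equal(nrow(sp$test_pairs), 0)
  expect_equal(nrow(sp$train_pairs), 2)
})

test_that("connected holdout preserves component counts on random graphs", {
  for (i in 1:20) {
    n <- sample(30:200, 1)
    g <- er_graph(n, 2.2 / n, seed = 400 + i)
    if (kg_n_edges(g) < 2) next
    sp <- connected_holdout(g, 0.3, seed = i)
    expect_equal(kg_n_components(training_graph(g, sp)), kg_n_components(g))
    # train and test partition the edge set
    expect_equal(nrow(sp$train_pairs) + nrow(sp$test_pairs), kg_n_edges(g))
    k1 <- kglink:::pair_key(sp$train_pairs[, 1], sp$train_pairs[, 2], n)
    k2 <- kglink:::pair_key(sp$test_pairs[, 1], sp$test_pairs[, 2], n)
    expect_length(intersect(k1, k2), 0)
  }
})

test_that("stratified node holdouts keep per-type shares and reproduce from seed", {
  g1 <- kg_from_pairs(clique_pairs(sprintf("n%02d", 1:10)))
  h <- stratified_node_holdout(g1, 0.3, n_repeats = 1, seed = 1)
  expect_equal(sum(h$set == "test"), 3)

  ids <- c(sprintf("a%03d", 1:100), sprintf("b%03d", 1:10))
  g2 <- knowledge_graph(
    data.frame(node_id = ids, node_type = rep(c("A", "B"), c(100, 10))),
    data.frame(source = ids[1], target = ids[2], edge_type = "t")[0, ]
  )
  h2 <- stratified_node_holdout(g2, 0.3, n_repeats = 5, seed = 3)
  for (r in 1:5) {
    hr <- h2[h2$holdout == r, ]
    expect_equal(sum(hr$set == "test" & startsWith(hr$node_id, "a")), 30)
    expect_equal(sum(hr$set == "test" & startsWith(hr$node_id, "b")), 3)
  }
  # repeats differ, reruns do not
  expect_false(identical(h2$set[h2$holdout == 1], h2$set[h2$holdout == 2]))
  h3 <- stratified_node_holdout(g2, 0.3, n_repeats = 5, seed = 3)
  expect_identical(h2, h3)

  # singleton types go to train with a warning
  g3 <- knowledge_graph(
    data.frame(node_id = c("a", "b", "c"), node_type = c("A", "A", "B")),
    data.frame(source = "a", target = "b", edge_type = "t")
  )
  expect_warning(h4 <- stratified_node_holdout(g3, 0.5, 1, seed = 1), "single member")
  expect_equal(h4$set[h4$node_id == "c"], "train")
})

test_that("negative sampling rejects existing edges and reports shortfalls", {
  k4 <- kg_from_pairs(clique_pairs(c("a", "b", "c", "d")))
  expect_error(sample_negative_edges(k4, 1, seed = 1), "shortfall")

  g <- er_graph(80, 0.08, seed = 6)
  neg <- sample_negative_edges(g, 200, seed = 2)
  expect_equal(nrow(neg), 200)
  expect_true(all(neg$from < neg$to))
  expect_false(any(has_edge(g, neg$source, neg$target)))
  keys <- kglink:::pair_key(neg$from, neg$to, kg_n_nodes(g))
  expect_false(any(duplicated(keys)))
  # exclusions are honoured
  neg2 <- sample_negative_edges(g, 50, exclusions = neg, seed = 3)
  keys2 <- kglink:::pair_key(neg2$from, neg2$to, kg_n_nodes(g))
  expect_length(intersect(keys, keys2), 0)
})

test_that("raw endpoint draws are degree-proportional (star graph marginal)", {
  g <- star_graph(4) # center degree 4, leaves 1: center marginal 4/8
  ends <- kglink:::draw_degree_endpoints(g, 20000, seed = 11)
  frac_center <- mean(c(ends[, 1], ends[, 2]) == match("c00", kg_nodes(g)$node_id))
  p <- 0.5
  expect_lte(abs(frac_center - p), 3 * sqrt(p * (1 - p) / 40000))
})

test_that("type-constrained negatives respect endpoint types", {
  gen <- generate_kg(dense_target_spec(1))
  g <- gen$graph
  tp <- tibble::tibble(type_a = "A", type_b = "B", weight = 1)
  neg <- sample_negative_edges(g, 300, type_pairs = tp, seed = 4)
  ta <- kg_nodes(g)$node_type[neg$from]
  tb <- kg_nodes(g)$node_type[neg$to]
  expect_true(all(pmin(ta, tb) == "A" & pmax(ta, tb) == "B"))
})

test_that("the unbiased pipeline guarantees zero false negatives and disjoint sets", {
  gen <- generate_kg(dense_target_spec(7))
  g <- gen$graph
  for (s in c(1, 2)) {
    fs <- unbiased_specific_edge_split(g, "A-B", 0.3, 1, seed = s)
    expect_equal(fs$fn_test, 0)
    expect_equal(fs$fn_train, 0)
    n <- kg_n_nodes(g)
    ktr <- kglink:::pair_key(fs$train_negative$from, fs$train_negative$to, n)
    kte <- kglink:::pair_key(fs$test_negative$from, fs$test_negative$to, n)
    expect_length(intersect(ktr, kte), 0)
    expect_true(all(fs$train_positive$edge_type == "A-B"))
    expect_true(all(fs$test_positive$edge_type == "A-B"))
    # negative sizes mirror the positive split at ratio 1
    expect_equal(nrow(fs$train_negative), nrow(fs$train_positive))
    expect_equal(nrow(fs$test_negative), nrow(fs$test_positive))
    # the training graph keeps the source component count
    expect_equal(kg_n_components(fs$training_graph), kg_n_components(g))
  }
  # 10x negative ratio variant needs a sparser target block
  gsp <- generate_kg(sparse_target_spec(8))$graph
  fs10 <- unbiased_specific_edge_split(gsp, "A-B", 0.3, 10, seed = 3)
  expect_equal(nrow(fs10$test_negative), 10 * nrow(fs10$test_positive))
  expect_equal(fs10$fn_test, 0)
})

test_that("the biased baseline leaks test positives on a dense target type", {
  gen <- generate_kg(dense_target_spec(5))
  g <- gen$graph
  fns <- vapply(1:5, function(s) {
    biased_specific_edge_split(g, "A-B", 0.3, 1, seed = s)$fn_test
  }, numeric(1))
  expect_true(all(fns >= 0))
  expect_gt(mean(fns), 5) # dense block: substantial leakage
  # unbiased on the same seeds is always exactly zero
  fnu <- vapply(1:5, function(s) {
    unbiased_specific_edge_split(g, "A-B", 0.3, 1, seed = s)$fn_test
  }, numeric(1))
  expect_equal(fnu, rep(0, 5))
})

test_that("a target type made of bridges yields no test positives and FN 0 even biased", {
  a <- sprintf("a%02d", 1:8)
  b <- sprintf("b%02d", 1:8)
  nodes <- data.frame(
    node_id = c(a, b), node_type = rep(c("A", "B"), each = 8)
  )
  cp <- clique_pairs(a)
  edges <- rbind(
    data.frame(source = cp[, 1], target = cp[, 2], edge_type = "A-A"),
    data.frame(source = a, target = b, edge_type = "A-B") # one bridge each
  )
  g <- knowledge_graph(nodes, edges)
  fs <- suppressWarnings(
    biased_specific_edge_split(g, "A-B", 0.3, 1, seed = 2)
  )
  expect_equal(nrow(fs$test_positive), 0)
  expect_equal(fs$fn_test, 0)
})

test_that("false-negative rate is exact arithmetic and matches a naive scan", {
  g <- er_graph(60, 0.08, seed = 12)
  ed <- kg_edges(g)
  cand <- tibble::tibble(
    source = c(ed$source[1], "n0001", "n0002", "n0003"),
    target = c(ed$target[1], "n0050", "n0051", "n0052")
  )
  # ensure the three constructed pairs are non-edges
  cand <- cand[c(TRUE, !has_edge(g, cand$source[-1], cand$target[-1])), ]
  expect_equal(false_negative_rate(cand, g), 100 * 1 / nrow(cand))
  expect_message(z <- false_negative_rate(cand[0, ], g), "convention")
  expect_equal(z, 0)

  set.seed(8)
  ids <- kg_nodes(g)$node_id
  rnd <- tibble::tibble(
    source = sample(ids, 1000, replace = TRUE),
    target = sample(ids, 1000, replace = TRUE)
  )
  rnd <- rnd[rnd$source != rnd$target, ]
  expect_equal(false_negative_rate(rnd, g), oracle_fn_rate(rnd, g))
})

test_that("splits persist to TSV with a manifest", {
  gen <- generate_kg(dense_target_spec(3))
  fs <- unbiased_specific_edge_split(gen$graph, "A-B", 0.3, 1, seed = 1)
  d <- tempfile()
  write_split(fs, gen$graph, d)
  expect_true(all(file.exists(file.path(d, c(
    "train_positive.tsv", "test_positive.tsv",
    "train_negative.tsv", "test_negative.tsv", "manifest.tsv"
  )))))
  man <- readr::read_tsv(file.path(d, "manifest.tsv"), show_col_types = FALSE)
  expect_equal(man$value[man$field == "fn_test_pct"], "0")
})
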