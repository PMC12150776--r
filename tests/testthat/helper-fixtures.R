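# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; expensive shared objects (the small preset
# graph and its embedding) are memoised for the duration of one test run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

preset_small <- function() {
  memo_fixture("preset_small", generate_kg(rnakg_like_preset("small")))
}

# desk-scale node2vec-BFS embedding of the small preset's full graph
preset_small_bfs_embedding <- function() {
  memo_fixture("preset_small_bfs_emb", {
    params <- node2vec_preset("bfs",
      dim = 10, walks_per_node = 10,
      walk_length = 80, epochs = 5, seed = 42
    )
    embed_graph(preset_small()$graph, params)
  })
}

# graph builders -------------------------------------------------------------

kg_from_pairs <- function(pairs, types = NULL, edge_type = "t") {
  ids <- sort(unique(c(pairs[, 1], pairs[, 2])))
  if (is.null(types)) types <- stats::setNames(rep("x", length(ids)), ids)
  knowledge_graph(
    data.frame(node_id = ids, node_type = unname(types[ids])),
    data.frame(source = pairs[, 1], target = pairs[, 2], edge_type = edge_type),
    quiet = TRUE
  )
}

clique_pairs <- function(ids) t(utils::combn(ids, 2))

two_cliques_graph <- function(size = 10) {
  a <- sprintf("a%02d", seq_len(size))
  b <- sprintf("b%02d", seq_len(size))
  kg_from_pairs(rbind(clique_pairs(a), clique_pairs(b)))
}

path_graph <- function(ids = c("a", "b", "c")) {
  kg_from_pairs(cbind(ids[-length(ids)], ids[-1]))
}

star_graph <- function(n_leaves = 4) {
  kg_from_pairs(cbind("c00", sprintf("l%02d", seq_len(n_leaves))))
}

# Erdos-Renyi graph over n string-labelled nodes, plus isolated nodes kept
er_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%04d", seq_len(n))
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pr)) < p
  knowledge_graph(
    data.frame(node_id = ids, node_type = "x"),
    data.frame(
      source = ids[pr[keep, 1]], target = ids[pr[keep, 2]], edge_type = "t"
    ),
    quiet = TRUE
  )
}

# dense planted target type used by the bias-direction checks: two equal
# types, 2 sub-communities, marginal A-B density 0.3, assortative everywhere
dense_target_spec <- function(seed) {
  kg_spec(
    n_nodes = 400, type_names = c("A", "B"), type_probs = c(0.5, 0.5),
    block_density = matrix(c(0.05, 0.3, 0.3, 0.05), 2, 2),
    n_communities = 2L, assortative = matrix(TRUE, 2, 2),
    ensure_connected = TRUE, seed = seed
  )
}

# sparser two-type variant with enough non-edges for 10x negative ratios
sparse_target_spec <- function(seed) {
  kg_spec(
    n_nodes = 600, type_names = c("A", "B"), type_probs = c(0.5, 0.5),
    block_density = matrix(0.02, 2, 2),
    n_communities = 2L, assortative = matrix(TRUE, 2, 2),
    ensure_connected = TRUE, seed = seed
  )
}

# independent oracles --------------------------------------------------------

# union-find connected-component count, independent of igraph
brute_force_n_components <- function(g) {
  n <- kg_n_nodes(g)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  p <- kglink:::kg_pairs(g)
  for (i in seq_len(nrow(p))) {
    ra <- find(p[i, 1])
    rb <- find(p[i, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# brute-force enumeration of the biased-walk weight rule
oracle_transition <- function(g, prev, curr, return_weight, explore_weight) {
  ed <- kg_edges(g)
  nb <- function(v) sort(unique(c(ed$target[ed$source == v], ed$source[ed$target == v])))
  nbr <- nb(curr)
  pn <- nb(prev)
  w <- vapply(nbr, function(x) {
    if (x == prev) return(return_weight)
    if (x %in% pn) return(1)
    explore_weight
  }, numeric(1))
  stats::setNames(w / sum(w), nbr)
}

# naive O(n_cand * m) edge-membership scan
oracle_fn_rate <- function(candidates, g) {
  ed <- kg_edges(g)
  hits <- 0
  for (i in seq_len(nrow(candidates))) {
    u <- candidates$source[i]
    v <- candidates$target[i]
    hits <- hits + any((ed$source == u & ed$target == v) | (ed$source == v & ed$target == u))
  }
  100 * hits / nrow(candidates)
}

cosine_matrix <- function(m) {
  m <- as.matrix(m)
  nm <- sqrt(rowSums(m^2))
  tcrossprod(m / pmax(nm, 1e-12))
}

# mean intra- minus inter-clique cosine separation for a two-clique embedding
clique_separation <- function(emb, size = 10) {
  cs <- cosine_matrix(emb)
  i1 <- seq_len(size)
  i2 <- size + seq_len(size)
  intra <- mean(c(cs[i1, i1][upper.tri(cs[i1, i1])], cs[i2, i2][upper.tri(cs[i2, i2])]))
  inter <- mean(cs[i1, i2])
  intra - inter
}
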