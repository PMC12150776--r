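#' node2vec hyperparameters
#'
#' Parameters of the biased second-order random walk and of the skip-gram
#' trainer. The walk bias follows the node2vec scheme: from the current node,
#' a candidate next step is weighted `return_weight` if it is the previous
#' node, 1 if it is adjacent to the previous node, and `explore_weight`
#' otherwise (the weights are the reciprocals 1/p and 1/q of the original
#' parameterisation). High `return_weight` keeps the walk near its origin
#' (breadth-first flavour), high `explore_weight` pushes it outward
#' (depth-first flavour).
#'
#' @param dim Embedding dimension.
#' @param return_weight,explore_weight Positive walk-bias weights (1/p, 1/q).
#' @param walks_per_node,walk_length Walk corpus size controls.
#' @param window Skip-gram context window.
#' @param negatives Negative samples per (center, context) pair.
#' @param epochs,learning_rate Skip-gram training schedule; the learning rate
#'   decays linearly.
#' @param seed Integer seed for walks and training.
#' @return Object of class `node2vec_params`.
#' @export
node2vec_params <- function(dim = 10, return_weight = 1, explore_weight = 1,
                            walks_per_node = 10, walk_length = 100, window = 5,
                            negatives = 5, epochs = 10, learning_rate = 0.05,
                            seed = 1L) {
  stopifnot(
    dim >= 1, return_weight > 0, explore_weight > 0, walks_per_node >= 1,
    walk_length >= 2, window >= 1, negatives >= 1, epochs >= 1, learning_rate > 0
  )
  structure(
    list(
      dim = as.integer(dim), return_weight = return_weight,
      explore_weight = explore_weight, walks_per_node = as.integer(walks_per_node),
      walk_length = as.integer(walk_length), window = as.integer(window),
      negatives = as.integer(negatives), epochs = as.integer(epochs),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "node2vec_params"
  )
}

#' Named node2vec walk settings
#'
#' The three walk regimes compared in the study design this package supports:
#' `"bfs"` (return_weight 5, explore_weight 0.2), `"dfs"` (0.2, 5) and
#' `"balanced"` (1, 1 — an unbiased first-order walk, DeepWalk-style).
#'
#' @param setting One of `"bfs"`, `"dfs"`, `"balanced"`.
#' @param ... Further arguments passed to [node2vec_params()].
#' @return Object of class `node2vec_params`.
#' @export
node2vec_preset <- function(setting = c("bfs", "dfs", "balanced"), ...) {
  setting <- match.arg(setting)
  w <- switch(setting,
    bfs = c(5, 0.2),
    dfs = c(0.2, 5),
    balanced = c(1, 1)
  )
  node2vec_params(return_weight = w[1], explore_weight = w[2], ...)
}

#' LINE hyperparameters
#'
#' LINE optimises, by per-sample stochastic updates on uniformly sampled
#' edges, either first-order proximity (directly connected nodes get similar
#' vectors) or second-order proximity (nodes with similar neighbourhoods get
#' similar vectors, via a separate context matrix), with negative sampling
#' from a degree^(3/4) noise distribution.
#'
#' @param dim Embedding dimension.
#' @param order 1 or 2.
#' @param total_samples Total edge samples; default `100 * |E|`, resolved at
#'   training time.
#' @param negatives Negative samples per edge sample.
#' @param learning_rate Initial learning rate (linear decay).
#' @param seed Integer seed.
#' @return Object of class `line_params`.
#' @export
line_params <- function(dim = 10, order = 1, total_samples = NULL,
                        negatives = 5, learning_rate = 0.025, seed = 1L) {
  stopifnot(dim >= 1, order %in% c(1, 2), negatives >= 1, learning_rate > 0)
  structure(
    list(
      dim = as.integer(dim), order = as.integer(order),
      total_samples = total_samples, negatives = as.integer(negatives),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "line_params"
  )
}

new_embedding_matrix <- function(mat, node_ids, method, params, seed, loss = NULL) {
  if (any(!is.finite(mat))) stop("embedding contains non-finite values", call. = FALSE)
  rownames(mat) <- node_ids
  structure(mat,
    class = c("embedding_matrix", class(mat)),
    method = method, params = params, seed = seed, loss = loss
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf(
    "<embedding_matrix> %d nodes x %d dims, method=%s, seed=%s\n",
    nrow(x), ncol(x), attr(x, "method"), attr(x, "seed")
  ))
  invisible(x)
}

#' Single-step transition distribution of the biased walk
#'
#' Returns the node2vec transition probabilities out of `curr` given the
#' previously visited node `prev`: unnormalised weight `return_weight` for
#' stepping back to `prev`, 1 for neighbours of `curr` adjacent to `prev`
#' (distance 1 from `prev`), `explore_weight` otherwise, normalised over the
#' neighbours of `curr`. With `prev = NULL` (first step of a walk) the
#' distribution is uniform.
#'
#' @param g A [knowledge_graph].
#' @param curr Current node id.
#' @param prev Previous node id (must be adjacent to `curr`), or `NULL`.
#' @param params A [node2vec_params()].
#' @return Tibble with `node_id` and `probability`, summing to 1.
#' @export
transition_distribution <- function(g, curr, prev = NULL, params = node2vec_params()) {
  ic <- match(as.character(curr), g$nodes$node_id)
  if (is.na(ic)) stop("unknown node id: ", curr, call. = FALSE)
  adj <- kg_adjacency(g)
  if (adj$degree[ic] == 0) stop("node '", curr, "' has no neighbors", call. = FALSE)
  nbr <- adj$neighbors[(adj$offsets[ic] + 1):adj$offsets[ic + 1]] + 1L
  if (is.null(prev)) {
    w <- rep(1, length(nbr))
  } else {
    ip <- match(as.character(prev), g$nodes$node_id)
    if (is.na(ip)) stop("unknown node id: ", prev, call. = FALSE)
    pn <- adj$neighbors[seq_len(adj$degree[ip]) + adj$offsets[ip]] + 1L
    if (!(ic %in% pn)) stop("prev must be adjacent to curr", call. = FALSE)
    w <- ifelse(nbr == ip, params$return_weight,
      ifelse(nbr %in% pn, 1, params$explore_weight)
    )
  }
  tibble::tibble(node_id = g$nodes$node_id[nbr], probability = w / sum(w))
}

#' Generate a biased random-walk corpus
#'
#' Starts `walks_per_node` walks from every non-isolated node (isolated nodes
#' are skipped with a message) and extends each to `walk_length` nodes using
#' the node2vec transition rule. Every consecutive pair in a walk is an edge
#' of the graph, and the corpus is reproducible from the seed.
#'
#' @param g A [knowledge_graph] with at least one edge.
#' @param params A [node2vec_params()].
#' @return Integer matrix (walks x walk_length) of dense node indices, with
#'   attribute `node_ids`; class `walk_corpus`.
#' @export
generate_walks <- function(g, params = node2vec_params()) {
  stopifnot(inherits(g, "knowledge_graph"), inherits(params, "node2vec_params"))
  if (kg_n_edges(g) == 0) stop("graph has no edges", call. = FALSE)
  adj <- kg_adjacency(g)
  starts <- which(adj$degree > 0)
  n_iso <- kg_n_nodes(g) - length(starts)
  if (n_iso > 0) message(sprintf("skipping %d isolated node(s) as walk starts", n_iso))
  walks <- generate_walks_cpp(
    adj$offsets, adj$neighbors, as.integer(starts - 1L),
    params$walks_per_node, params$walk_length,
    params$return_weight, params$explore_weight, params$seed
  ) + 1L
  structure(walks, node_ids = g$nodes$node_id, class = c("walk_corpus", class(walks)))
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling: for each (center, context) pair within
#' the window, ascend `log sigma(u_ctx . v_center)` plus negative terms with
#' noise drawn from the corpus unigram distribution raised to 3/4. The mean
#' per-epoch loss trace is stored in the result's `loss` attribute.
#'
#' @param walks A `walk_corpus` from [generate_walks()].
#' @param params The [node2vec_params()] used to train.
#' @return An `embedding_matrix` (rows aligned to the graph's dense index).
#' @export
train_skipgram <- function(walks, params = node2vec_params()) {
  if (length(walks) == 0) stop("empty walk corpus", call. = FALSE)
  node_ids <- attr(walks, "node_ids")
  fit <- train_skipgram_cpp(
    unclass(walks) - 1L, length(node_ids), params$dim, params$window,
    params$negatives, params$epochs, params$learning_rate, params$seed
  )
  new_embedding_matrix(fit$embedding, node_ids, "node2vec", params, params$seed, fit$loss)
}

#' Train LINE embeddings
#'
#' @param g A [knowledge_graph] with at least one edge.
#' @param params A [line_params()].
#' @return An `embedding_matrix`.
#' @export
train_line <- function(g, params = line_params()) {
  stopifnot(inherits(g, "knowledge_graph"), inherits(params, "line_params"))
  p <- kg_pairs(g)
  if (nrow(p) == 0) stop("graph has no edges", call. = FALSE)
  total <- if (is.null(params$total_samples)) 100 * nrow(p) else params$total_samples
  fit <- train_line_cpp(
    as.integer(p[, 1] - 1L), as.integer(p[, 2] - 1L), kg_n_nodes(g),
    params$dim, params$order, as.double(total), params$negatives,
    params$learning_rate, params$seed
  )
  method <- paste0("line", params$order)
  new_embedding_matrix(fit$embedding, g$nodes$node_id, method, params, params$seed, fit$loss)
}

#' Embed a graph with either method
#'
#' Dispatches on the parameter object: [node2vec_params()] runs
#' [generate_walks()] + [train_skipgram()]; [line_params()] runs
#' [train_line()].
#'
#' @param g A [knowledge_graph].
#' @param params A [node2vec_params()] or [line_params()].
#' @return An `embedding_matrix`.
#' @export
embed_graph <- function(g, params) {
  if (inherits(params, "node2vec_params")) {
    train_skipgram(generate_walks(g, params), params)
  } else if (inherits(params, "line_params")) {
    train_line(g, params)
  } else {
    stop("params must be node2vec_params or line_params", call. = FALSE)
  }
}

#' Persist an embedding with its provenance
#'
#' Writes the vectors as TSV (`node_id` + one column per dimension) plus a
#' sidecar `<path>.meta.tsv` with method, seed and parameters.
#'
#' @param emb An `embedding_matrix`.
#' @param path Output TSV path.
#' @return `emb`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- tibble::as_tibble(as.matrix(emb), .name_repair = ~ paste0("d", seq_along(.x)))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(node_id = rownames(emb)), df), path)
  p <- attr(emb, "params")
  meta <- tibble::tibble(
    field = c("method", "seed", names(p)),
    value = c(
      attr(emb, "method"), as.character(attr(emb, "seed")),
      vapply(p, function(x) paste(format(x), collapse = ","), character(1))
    )
  )
  readr::write_tsv(meta, paste0(path, ".meta.tsv"))
  invisible(emb)
}
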