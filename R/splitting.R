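#' Connectivity-preserving ("Connected Monte-Carlo") edge holdout
#'
#' Splits the undirected edge set into positive train and positive test sets
#' such that removing the test edges does not change the number of connected
#' components: a random spanning forest (Kruskal on a uniformly random edge
#' permutation) is forced into the train set, and the remaining edges are
#' randomly assigned so the test set is as close as possible to
#' `test_fraction * |E|` without breaking the forest constraint. If the graph
#' is itself a forest every edge is a bridge, the test set is empty and a
#' warning is emitted.
#'
#' The split operates on unique node pairs; parallel typed edges on a pair
#' follow their pair.
#'
#' @param g A [knowledge_graph] with at least one edge.
#' @param test_fraction Fraction of edges to hold out, in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `edge_split`: list with typed edge tibbles
#'   `train` and `test` (`from`, `to`, `edge_type`), pair matrices
#'   `train_pairs`/`test_pairs`, and bookkeeping (`n_components`,
#'   `test_fraction`, `seed`).
#' @export
connected_holdout <- function(g, test_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(g, "knowledge_graph"), test_fraction > 0, test_fraction < 1)
  p <- kg_pairs(g)
  m <- nrow(p)
  if (m < 1) stop("graph has no edges", call. = FALSE)
  local_seed(as.integer(seed))

  # random spanning forest: minimum spanning forest under i.i.d. uniform
  # edge weights (equivalent to Kruskal on a random edge permutation)
  ig <- igraph::graph_from_edgelist(p, directed = FALSE)
  igraph::E(ig)$idx <- seq_len(m)
  msf <- igraph::mst(ig, weights = stats::runif(m))
  in_forest <- logical(m)
  in_forest[igraph::E(msf)$idx] <- TRUE
  free <- which(!in_forest)
  n_test <- min(round(test_fraction * m), length(free))
  if (length(free) == 0) {
    warning("graph is a forest: every edge is a bridge, test set is empty", call. = FALSE)
  }
  test_idx <- if (n_test > 0) sample(free, n_test) else integer()
  is_test <- logical(m)
  is_test[test_idx] <- TRUE

  n <- kg_n_nodes(g)
  keys <- pair_key(p[, 1], p[, 2], n)
  ekeys <- pair_key(g$edges$from, g$edges$to, n)
  edge_is_test <- ekeys %in% keys[is_test]

  structure(
    list(
      train = g$edges[!edge_is_test, ],
      test = g$edges[edge_is_test, ],
      train_pairs = p[!is_test, , drop = FALSE],
      test_pairs = p[is_test, , drop = FALSE],
      n_components = kg_n_components(g),
      test_fraction = test_fraction,
      seed = as.integer(seed)
    ),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(
    "<edge_split> %d train / %d test pairs (target test fraction %.2f)\n",
    nrow(x$train_pairs), nrow(x$test_pairs), x$test_fraction
  ))
  invisible(x)
}

#' Training graph of an edge split
#'
#' The graph on the full node set containing only the positive training
#' edges; this is the graph that must be embedded to avoid test leakage.
#'
#' @param g The source [knowledge_graph].
#' @param split An `edge_split` (or a `filtered_split`'s underlying split).
#' @return A [knowledge_graph].
#' @export
training_graph <- function(g, split) kg_with_edges(g, split$train)

#' Stratified node holdouts
#'
#' Repeated stratified train/test partitions of the node set: within every
#' node type, a `test_fraction` share (within one node) is held out. Types
#' with a single member go entirely to train with a warning. Repeats differ
#' from each other but the whole sequence is reproducible from the seed.
#'
#' @param g A [knowledge_graph].
#' @param test_fraction Held-out share per type.
#' @param n_repeats Number of holdout repetitions.
#' @param seed Integer seed.
#' @return Tibble with columns `holdout` (1..n_repeats), `node_id`, `set`
#'   (`"train"`/`"test"`).
#' @export
stratified_node_holdout <- function(g, test_fraction = 0.3, n_repeats = 5, seed = 1L) {
  stratified_label_holdout(
    g$nodes$node_id, g$nodes$node_type, test_fraction, n_repeats, seed
  )
}

# shared stratified splitter over an arbitrary labelled id vector
stratified_label_holdout <- function(ids, labels, test_fraction, n_repeats, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1)
  local_seed(as.integer(seed))
  singletons <- names(which(table(labels) < 2))
  if (length(singletons) > 0) {
    warning(
      "type(s) with a single member assigned to train: ",
      paste(singletons, collapse = ", "),
      call. = FALSE
    )
  }
  purrr::map_dfr(seq_len(n_repeats), function(r) {
    set <- rep("train", length(ids))
    for (lv in unique(labels)) {
      members <- which(labels == lv)
      nl <- length(members)
      if (nl < 2) next
      n_test <- min(round(test_fraction * nl), nl - 1)
      if (n_test > 0) set[sample(members, n_test)] <- "test"
    }
    tibble::tibble(holdout = r, node_id = ids, set = set)
  })
}

#' Degree-aware negative edge sampling
#'
#' Draws candidate non-edges with both endpoints sampled independently with
#' probability proportional to their degree in `g`, so that the endpoint
#' degree distribution of the negatives matches that of the positive edges
#' (a node of degree d appears among positive edge endpoints with frequency
#' proportional to d). Self-pairs, pairs in `forbidden` or `exclusions`, and
#' duplicates are rejection-resampled. Fails with a shortfall error when
#' `max_rejections * n_samples` draws do not yield `n_samples` pairs.
#'
#' @param g A [knowledge_graph]; degrees are always taken from this graph.
#' @param n_samples Number of negative pairs required.
#' @param exclusions Optional extra pair set to avoid: matrix/data frame with
#'   dense-index columns `from`, `to`.
#' @param forbidden Pair set that defines "existing" edges for rejection;
#'   default the full edge set of `g`. (The biased pipeline passes the
#'   filtered train pairs here instead.)
#' @param type_pairs Optional tibble (`type_a`, `type_b`, `weight`)
#'   restricting endpoint node types: a row is chosen with probability
#'   proportional to `weight`, then one endpoint is drawn from each type.
#' @param seed Integer seed.
#' @param max_rejections Attempt budget multiplier before declaring a
#'   shortfall.
#' @return Tibble `source`, `target`, `from`, `to` (canonical from < to).
#' @export
sample_negative_edges <- function(g, n_samples, exclusions = NULL, forbidden = NULL,
                                  type_pairs = NULL, seed = 1L, max_rejections = 100) {
  stopifnot(inherits(g, "knowledge_graph"), n_samples >= 1)
  n <- kg_n_nodes(g)
  deg <- node_degrees(g)$degree
  if (sum(deg > 0) < 2) stop("need at least 2 nodes of nonzero degree", call. = FALSE)
  local_seed(as.integer(seed))

  forbid_keys <- if (is.null(forbidden)) {
    kg_pair_keys(g)
  } else {
    fb <- as.matrix(as.data.frame(forbidden)[, c("from", "to")])
    pair_key(pmin(fb[, 1], fb[, 2]), pmax(fb[, 1], fb[, 2]), n)
  }
  avoid_keys <- forbid_keys
  if (!is.null(exclusions) && NROW(exclusions) > 0) {
    ex <- as.matrix(as.data.frame(exclusions)[, c("from", "to")])
    avoid_keys <- c(avoid_keys, pair_key(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2]), n))
  }

  if (!is.null(type_pairs)) {
    tp <- as.data.frame(type_pairs)
    if (is.null(tp$weight)) tp$weight <- 1
    pools_a <- lapply(tp$type_a, function(t) which(g$nodes$node_type == t))
    pools_b <- lapply(tp$type_b, function(t) which(g$nodes$node_type == t))
    ok <- vapply(seq_len(nrow(tp)), function(i) {
      sum(deg[pools_a[[i]]]) > 0 && sum(deg[pools_b[[i]]]) > 0
    }, logical(1))
    if (!any(ok)) stop("no usable endpoint type pair for negative sampling", call. = FALSE)
    tp <- tp[ok, , drop = FALSE]
    pools_a <- pools_a[ok]
    pools_b <- pools_b[ok]
    row_prob <- tp$weight / sum(tp$weight)
  }

  draw_batch <- function(size) {
    if (is.null(type_pairs)) {
      uv <- draw_degree_endpoints(g, size)
      u <- uv[, 1]
      v <- uv[, 2]
    } else {
      ridx <- sample.int(nrow(tp), size, replace = TRUE, prob = row_prob)
      u <- integer(size)
      v <- integer(size)
      for (i in unique(ridx)) {
        sel <- ridx == i
        pa <- pools_a[[i]]
        pb <- pools_b[[i]]
        u[sel] <- pa[sample.int(length(pa), sum(sel), replace = TRUE, prob = deg[pa])]
        v[sel] <- pb[sample.int(length(pb), sum(sel), replace = TRUE, prob = deg[pb])]
      }
    }
    cbind(pmin(u, v), pmax(u, v))
  }

  got <- matrix(integer(), ncol = 2)
  got_keys <- numeric()
  attempts <- 0
  budget <- max_rejections * n_samples
  while (nrow(got) < n_samples && attempts < budget) {
    size <- min(max(2 * (n_samples - nrow(got)), 100), budget - attempts)
    attempts <- attempts + size
    cand <- draw_batch(size)
    keys <- pair_key(cand[, 1], cand[, 2], n)
    keep <- cand[, 1] != cand[, 2] & !(keys %in% avoid_keys) &
      !(keys %in% got_keys) & !duplicated(keys)
    got <- rbind(got, cand[keep, , drop = FALSE])
    got_keys <- c(got_keys, keys[keep])
  }
  if (nrow(got) < n_samples) {
    stop(sprintf(
      "negative sampling shortfall: %d of %d pairs after %d draws",
      nrow(got), n_samples, attempts
    ), call. = FALSE)
  }
  got <- got[seq_len(n_samples), , drop = FALSE]
  tibble::tibble(
    source = g$nodes$node_id[got[, 1]],
    target = g$nodes$node_id[got[, 2]],
    from = got[, 1], to = got[, 2]
  )
}

# Raw degree-proportional endpoint draws (before any rejection): each
# endpoint independently with probability proportional to its degree in g.
draw_degree_endpoints <- function(g, size, seed = NULL) {
  if (!is.null(seed)) local_seed(as.integer(seed))
  n <- kg_n_nodes(g)
  deg <- node_degrees(g)$degree
  cbind(
    sample.int(n, size, replace = TRUE, prob = deg),
    sample.int(n, size, replace = TRUE, prob = deg)
  )
}

#' False-negative rate of a candidate negative set
#'
#' Percentage of candidate "negative" pairs that are in fact edges of `g`.
#' Empty candidate sets return 0 by convention (with a message).
#'
#' @param candidates Data frame or matrix of pairs; either dense-index
#'   columns `from`/`to` or id columns `source`/`target`.
#' @param g A [knowledge_graph].
#' @return Percentage in `[0, 100]`.
#' @export
false_negative_rate <- function(candidates, g) {
  cd <- as.data.frame(candidates)
  if (NROW(cd) == 0) {
    message("empty candidate set: false-negative rate 0 by convention")
    return(0)
  }
  if (all(c("from", "to") %in% names(cd))) {
    fr <- cd$from
    to <- cd$to
  } else {
    fr <- match(as.character(cd$source), g$nodes$node_id)
    to <- match(as.character(cd$target), g$nodes$node_id)
    if (anyNA(fr) || anyNA(to)) stop("candidate references unknown node id", call. = FALSE)
  }
  k <- pair_key(pmin(fr, to), pmax(fr, to), kg_n_nodes(g))
  100 * mean(k %in% kg_pair_keys(g))
}

# observed endpoint-type pairs of a set of typed edges, with counts
edge_type_endpoint_pairs <- function(g, edges) {
  ta <- g$nodes$node_type[edges$from]
  tb <- g$nodes$node_type[edges$to]
  tibble::tibble(type_a = pmin(ta, tb), type_b = pmax(ta, tb)) |>
    dplyr::count(.data$type_a, .data$type_b, name = "weight")
}

specific_split_engine <- function(g, target_edge_type, test_fraction, negative_ratio,
                                  seed, type_constrained, unbiased) {
  stopifnot(inherits(g, "knowledge_graph"), negative_ratio >= 1)
  typed <- dplyr::filter(g$edges, .data$edge_type == target_edge_type)
  if (nrow(typed) < 2) {
    stop("need at least 2 edges of type '", target_edge_type, "'", call. = FALSE)
  }

  split <- connected_holdout(g, test_fraction, seed)
  pos_train <- dplyr::filter(split$train, .data$edge_type == target_edge_type)
  pos_test <- dplyr::filter(split$test, .data$edge_type == target_edge_type)

  type_pairs <- if (type_constrained) edge_type_endpoint_pairs(g, typed) else NULL
  n_tr <- nrow(pos_train)
  n_te <- nrow(pos_test)
  n_neg <- negative_ratio * (n_tr + n_te)

  forbidden <- if (unbiased) NULL else pos_train[, c("from", "to")]
  negatives <- sample_negative_edges(
    g, n_neg,
    forbidden = forbidden, type_pairs = type_pairs,
    seed = seed + 1L
  )
  local_seed(as.integer(seed) + 2L)
  shuf <- negatives[sample.int(nrow(negatives)), ]
  n_te_neg <- negative_ratio * n_te
  neg_test <- shuf[seq_len(n_te_neg), , drop = FALSE]
  neg_train <- shuf[setdiff(seq_len(nrow(shuf)), seq_len(n_te_neg)), , drop = FALSE]

  fn_test <- suppressMessages(false_negative_rate(neg_test, g))
  fn_train <- suppressMessages(false_negative_rate(neg_train, g))

  structure(
    list(
      target_edge_type = target_edge_type,
      unbiased = unbiased,
      train_positive = pos_train,
      test_positive = pos_test,
      train_negative = neg_train,
      test_negative = neg_test,
      negative_pool = negatives,
      edge_split = split,
      training_graph = training_graph(g, split),
      fn_test = fn_test,
      fn_train = fn_train,
      negative_ratio = negative_ratio,
      seed = as.integer(seed)
    ),
    class = "filtered_split"
  )
}

#' Leakage-free train/test construction for one edge type
#'
#' The unbiased 7-step pipeline for edge prediction restricted to a single
#' edge type:
#' 1. split the full graph into positive train/test by [connected_holdout()];
#' 2. keep the training graph (all its edges, all types) for embedding —
#'    embeddings must be computed on it, not on the full graph;
#' 3. filter positive train and test edges to the target type;
#' 4. sample the negative pool degree-aware from the full graph, rejecting
#'    any pair that is an edge of the full graph (of any type) — this is the
#'    zero-false-negative guarantee;
#' 5. partition the pool disjointly into train/test negatives mirroring the
#'    positive split proportions;
#' 6.-7. training and testing are the caller's job (see
#'    [run_specific_edge_prediction()]).
#'
#' By default negatives are endpoint-type-constrained: pairs are drawn only
#' among node-type combinations actually observed for the target edge type
#' (otherwise negatives would be trivially separable by type alone).
#'
#' @param g The full [knowledge_graph].
#' @param target_edge_type Edge type label to predict.
#' @param test_fraction Positive holdout fraction.
#' @param negative_ratio Negatives per positive (1 default; 10 for the
#'   stress-test variant).
#' @param seed Integer seed.
#' @param type_constrained Restrict negative endpoint types (default TRUE).
#' @return A `filtered_split`: positive/negative train/test edge tibbles, the
#'   underlying `edge_split`, the `training_graph` to embed, and the measured
#'   false-negative rates `fn_test`/`fn_train` (0 here by construction).
#' @export
unbiased_specific_edge_split <- function(g, target_edge_type, test_fraction = 0.3,
                                         negative_ratio = 1, seed = 1L,
                                         type_constrained = TRUE) {
  specific_split_engine(
    g, target_edge_type, test_fraction, negative_ratio, seed,
    type_constrained,
    unbiased = TRUE
  )
}

#' Biased baseline: negatives rejected only against the filtered train graph
#'
#' Identical to [unbiased_specific_edge_split()] except that candidate
#' negatives are rejected only against the filtered positive *training*
#' edges rather than the full graph. Positive pairs that fell into the test
#' set (or carry another edge type) can therefore be sampled as "negatives",
#' producing false negatives; the realised rates are reported in the result's
#' `fn_test`/`fn_train` fields.
#'
#' @inheritParams unbiased_specific_edge_split
#' @return A `filtered_split` with nonzero `fn_test` possible.
#' @export
biased_specific_edge_split <- function(g, target_edge_type, test_fraction = 0.3,
                                       negative_ratio = 1, seed = 1L,
                                       type_constrained = TRUE) {
  specific_split_engine(
    g, target_edge_type, test_fraction, negative_ratio, seed,
    type_constrained,
    unbiased = FALSE
  )
}

#' @export
print.filtered_split <- function(x, ...) {
  cat(sprintf(
    "<filtered_split> type '%s' (%s): %d/%d positive, %d/%d negative train/test; FN%% test = %.2f\n",
    x$target_edge_type, if (x$unbiased) "unbiased" else "biased",
    nrow(x$train_positive), nrow(x$test_positive),
    nrow(x$train_negative), nrow(x$test_negative), x$fn_test
  ))
  invisible(x)
}

#' Persist a split as edge-list TSVs plus a manifest
#'
#' Writes one TSV per split member (`train_positive`, `test_positive`,
#' `train_negative`, `test_negative`) and a `manifest.tsv` with seed, sizes,
#' target type and false-negative rates.
#'
#' @param split A `filtered_split`.
#' @param g The source graph (for node identifiers).
#' @param dir Output directory (created if needed).
#' @return `split`, invisibly.
#' @export
write_split <- function(split, g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_ids <- function(e) {
    tibble::tibble(
      source = g$nodes$node_id[e$from], target = g$nodes$node_id[e$to],
      edge_type = if ("edge_type" %in% names(e)) e$edge_type else split$target_edge_type
    )
  }
  for (member in c("train_positive", "test_positive", "train_negative", "test_negative")) {
    readr::write_tsv(as_ids(split[[member]]), file.path(dir, paste0(member, ".tsv")))
  }
  manifest <- tibble::tibble(
    field = c(
      "target_edge_type", "unbiased", "seed", "negative_ratio",
      "n_train_positive", "n_test_positive", "n_train_negative",
      "n_test_negative", "fn_train_pct", "fn_test_pct"
    ),
    value = as.character(c(
      split$target_edge_type, split$unbiased, split$seed, split$negative_ratio,
      nrow(split$train_positive), nrow(split$test_positive),
      nrow(split$train_negative), nrow(split$test_negative),
      format(split$fn_train), format(split$fn_test)
    ))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(split)
}
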