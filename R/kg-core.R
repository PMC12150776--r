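#' Typed undirected knowledge graph
#'
#' `knowledge_graph()` builds the package's central data structure from a node
#' table and an edge table. The graph is undirected and unweighted; nodes carry
#' a categorical `node_type` and edges a categorical `edge_type`. Internally
#' every node is assigned a dense integer index in `1:n` obtained by sorting
#' the node identifiers, so that the index is reproducible from the node set
#' alone. Edges are stored in canonical form with the smaller dense index
#' first; duplicate rows and both orientations of the same pair collapse to a
#' single row per (pair, edge type), and self-loops are dropped with a message.
#'
#' A node pair may carry several typed edges (parallel relations are common in
#' biomedical knowledge graphs). Topological operations — degree, components,
#' random walks, holdouts — see each pair once; type-addressed operations see
#' the typed multiplicities.
#'
#' @param nodes Data frame with columns `node_id` (character) and `node_type`.
#' @param edges Data frame with columns `source`, `target` and `edge_type`,
#'   where `source`/`target` are node identifiers. May have zero rows.
#' @param quiet Suppress the dropped self-loop message.
#'
#' @return An object of class `knowledge_graph`: a list with tibbles `nodes`
#'   (`node_id`, `node_type`) and `edges` (`from`, `to`, `edge_type`, with
#'   `from < to` dense indices).
#' @export
knowledge_graph <- function(nodes, edges, quiet = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("node_id", "node_type") %in% names(nodes))) {
    stop("node table must have columns 'node_id' and 'node_type'", call. = FALSE)
  }
  if (nrow(edges) > 0 && !all(c("source", "target", "edge_type") %in% names(edges))) {
    stop("edge table must have columns 'source', 'target' and 'edge_type'", call. = FALSE)
  }
  nodes <- tibble::tibble(
    node_id = as.character(nodes$node_id),
    node_type = as.character(nodes$node_type)
  )
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in node table", call. = FALSE)
  }
  nodes <- dplyr::arrange(nodes, .data$node_id)

  if (nrow(edges) == 0) {
    ed <- tibble::tibble(from = integer(), to = integer(), edge_type = character())
  } else {
    from <- match(as.character(edges$source), nodes$node_id)
    to <- match(as.character(edges$target), nodes$node_id)
    bad <- which(is.na(from) | is.na(to))
    if (length(bad) > 0) {
      b <- bad[1]
      stop(sprintf(
        "edge row %d references unknown node id ('%s' -- '%s')",
        b, edges$source[b], edges$target[b]
      ), call. = FALSE)
    }
    loops <- from == to
    if (any(loops) && !quiet) {
      message(sprintf("dropped %d self-loop edge row(s)", sum(loops)))
    }
    lo <- pmin(from, to)[!loops]
    hi <- pmax(from, to)[!loops]
    ed <- tibble::tibble(
      from = lo,
      to = hi,
      edge_type = as.character(edges$edge_type)[!loops]
    )
    ed <- dplyr::distinct(ed)
    ed <- dplyr::arrange(ed, .data$from, .data$to, .data$edge_type)
  }
  structure(list(nodes = nodes, edges = ed), class = "knowledge_graph")
}

#' Read a knowledge graph from TSV files
#'
#' Expects a node table with header `node_id<TAB>node_type` and an edge list
#' with header `source<TAB>target<TAB>edge_type`.
#'
#' @param node_path,edge_path Paths to the two tab-separated files.
#' @inheritParams knowledge_graph
#' @return A [knowledge_graph] object.
#' @export
read_kg <- function(node_path, edge_path, quiet = FALSE) {
  nodes <- readr::read_tsv(node_path, col_types = readr::cols(.default = readr::col_character()))
  edges <- readr::read_tsv(edge_path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("node_id", "node_type") %in% names(nodes))) {
    stop("malformed node table: need columns node_id, node_type", call. = FALSE)
  }
  if (!all(c("source", "target", "edge_type") %in% names(edges))) {
    stop("malformed edge list: need columns source, target, edge_type", call. = FALSE)
  }
  knowledge_graph(nodes, edges, quiet = quiet)
}

#' Write a knowledge graph to TSV files
#'
#' Inverse of [read_kg()]: writes the node table and the canonical edge list.
#' A read/write round trip reproduces the graph exactly.
#'
#' @param g A [knowledge_graph].
#' @param node_path,edge_path Output paths.
#' @return `g`, invisibly.
#' @export
write_kg <- function(g, node_path, edge_path) {
  stopifnot(inherits(g, "knowledge_graph"))
  readr::write_tsv(g$nodes, node_path)
  readr::write_tsv(kg_edges(g), edge_path)
  invisible(g)
}

#' Node and edge tables of a graph
#'
#' `kg_nodes()` returns the node tibble; `kg_edges()` the typed edge tibble
#' with node identifiers (`source`, `target`, `edge_type`).
#' @param g A [knowledge_graph].
#' @return A tibble.
#' @export
kg_nodes <- function(g) g$nodes

#' @rdname kg_nodes
#' @export
kg_edges <- function(g) {
  tibble::tibble(
    source = g$nodes$node_id[g$edges$from],
    target = g$nodes$node_id[g$edges$to],
    edge_type = g$edges$edge_type
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> %d nodes (%d types), %d edges (%d pairs, %d edge types)\n",
    kg_n_nodes(x), dplyr::n_distinct(x$nodes$node_type),
    nrow(x$edges), nrow(kg_pairs(x)), dplyr::n_distinct(x$edges$edge_type)
  ))
  invisible(x)
}

#' Graph sizes
#'
#' `kg_n_nodes()` counts nodes; `kg_n_edges()` counts undirected edges, either
#' as unique node pairs (`typed = FALSE`, the topological edge count) or as
#' typed (pair, edge type) records.
#' @param g A [knowledge_graph].
#' @param typed Count typed records instead of unique pairs.
#' @return Integer.
#' @export
kg_n_nodes <- function(g) nrow(g$nodes)

#' @rdname kg_n_nodes
#' @export
kg_n_edges <- function(g, typed = FALSE) {
  if (typed) nrow(g$edges) else nrow(kg_pairs(g))
}

# Unique undirected pairs as an integer matrix (from < to).
kg_pairs <- function(g) {
  p <- dplyr::distinct(g$edges, .data$from, .data$to)
  cbind(from = p$from, to = p$to)
}

# Collision-free numeric key for a canonical pair, exact for n < 2^26.
pair_key <- function(from, to, n) (from - 1) * as.double(n) + to

kg_pair_keys <- function(g) {
  p <- kg_pairs(g)
  pair_key(p[, 1], p[, 2], kg_n_nodes(g))
}

#' Edge membership, orientation-independent
#'
#' @param g A [knowledge_graph].
#' @param u,v Node identifiers (vectors of equal length).
#' @return Logical vector: is `{u, v}` an edge of `g` (any edge type)?
#' @export
has_edge <- function(g, u, v) {
  iu <- match(as.character(u), g$nodes$node_id)
  iv <- match(as.character(v), g$nodes$node_id)
  if (anyNA(iu) || anyNA(iv)) stop("unknown node id", call. = FALSE)
  k <- pair_key(pmin(iu, iv), pmax(iu, iv), kg_n_nodes(g))
  k %in% kg_pair_keys(g)
}

#' Node degrees
#'
#' Degree of every node over unique undirected pairs (parallel typed edges on
#' the same pair count once); isolated nodes have degree 0. The degrees sum to
#' twice the number of pairs.
#'
#' @param g A [knowledge_graph].
#' @return Tibble with `node_id`, `node_type`, `degree`.
#' @export
node_degrees <- function(g) {
  p <- kg_pairs(g)
  deg <- tabulate(c(p[, 1], p[, 2]), nbins = kg_n_nodes(g))
  tibble::tibble(g$nodes, degree = deg)
}

#' Connected components
#'
#' `kg_components()` assigns every node to a connected component;
#' `kg_n_components()` returns only the count. Two nodes share a component iff
#' some path joins them.
#'
#' @param g A [knowledge_graph].
#' @return `kg_components()`: tibble `node_id`, `component` (integer);
#'   `kg_n_components()`: integer.
#' @export
kg_components <- function(g) {
  memb <- kg_component_membership(g)
  tibble::tibble(node_id = g$nodes$node_id, component = as.integer(memb))
}

#' @rdname kg_components
#' @export
kg_n_components <- function(g) {
  if (kg_n_nodes(g) == 0) return(0L)
  max(kg_component_membership(g))
}

# membership over dense indices, deterministic labelling
kg_component_membership <- function(g) {
  n <- kg_n_nodes(g)
  if (n == 0) return(integer())
  p <- kg_pairs(g)
  ig <- igraph::graph_from_edgelist(p, directed = FALSE)
  nv <- igraph::vcount(ig)
  memb <- integer(n)
  if (nv > 0) memb[seq_len(nv)] <- igraph::components(ig)$membership
  iso <- memb == 0L
  memb[iso] <- if (any(!iso)) max(memb) + seq_len(sum(iso)) else seq_len(sum(iso))
  memb
}

#' Induce a view: subgraph by node and edge types
#'
#' A "view" is the subgraph induced by a set of node types and a set of edge
#' types: nodes of other types are removed, typed edges of other types are
#' removed, and an edge survives only if both its endpoints do. Surviving
#' nodes left without edges are retained as isolated nodes. Selecting all
#' types returns a graph equal to the input; the operation is idempotent.
#'
#' @param g A [knowledge_graph].
#' @param node_types,edge_types Character vectors of labels to keep, or `NULL`
#'   to keep all. Unknown labels trigger a warning and are ignored.
#' @return A [knowledge_graph].
#' @export
filter_view <- function(g, node_types = NULL, edge_types = NULL) {
  stopifnot(inherits(g, "knowledge_graph"))
  if (!is.null(node_types)) {
    unknown <- setdiff(node_types, unique(g$nodes$node_type))
    if (length(unknown) > 0) {
      warning("ignoring unknown node type(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(edge_types)) {
    unknown <- setdiff(edge_types, unique(g$edges$edge_type))
    if (length(unknown) > 0) {
      warning("ignoring unknown edge type(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  keep_nodes <- if (is.null(node_types)) g$nodes else {
    dplyr::filter(g$nodes, .data$node_type %in% node_types)
  }
  ed <- kg_edges(g)
  if (!is.null(edge_types)) ed <- dplyr::filter(ed, .data$edge_type %in% edge_types)
  ed <- dplyr::filter(ed, .data$source %in% keep_nodes$node_id, .data$target %in% keep_nodes$node_id)
  knowledge_graph(keep_nodes, ed, quiet = TRUE)
}

# Subgraph with the same node set but only the given typed edge rows.
# `edges` is a tibble with from/to (dense indices of g) and edge_type.
kg_with_edges <- function(g, edges) {
  structure(
    list(
      nodes = g$nodes,
      edges = dplyr::arrange(
        tibble::tibble(
          from = as.integer(edges$from), to = as.integer(edges$to),
          edge_type = as.character(edges$edge_type)
        ),
        .data$from, .data$to, .data$edge_type
      )
    ),
    class = "knowledge_graph"
  )
}

# CSR adjacency over unique pairs: 0-based offsets/neighbors, each
# neighbor list sorted ascending (needed by the walk kernel's binary search).
kg_adjacency <- function(g) {
  n <- kg_n_nodes(g)
  p <- kg_pairs(g)
  ends <- c(p[, 1], p[, 2])
  nbrs <- c(p[, 2], p[, 1])
  o <- order(ends, nbrs)
  ends <- ends[o]
  nbrs <- nbrs[o]
  deg <- tabulate(ends, nbins = n)
  list(
    offsets = c(0L, cumsum(deg)),
    neighbors = as.integer(nbrs - 1L),
    degree = deg
  )
}
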