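#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-holdout records of a task result
#'
#' @param x A `task_result`.
#' @param ... Unused.
#' @return The per-holdout metric tibble (one row per holdout).
#' @exportS3Method generics::tidy
tidy.task_result <- function(x, ...) x$results

#' One-row summary of a task result
#'
#' @param x A `task_result`.
#' @param ... Unused.
#' @return One-row tibble: task name, number of holdouts, and `<metric>_mean`
#'   / `<metric>_sd` columns.
#' @exportS3Method generics::glance
glance.task_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary,
    names_from = "metric", values_from = c("mean", "sd"),
    names_glue = "{metric}_{.value}"
  )
  dplyr::bind_cols(
    tibble::tibble(task = x$task, n_holdouts = nrow(x$results)), wide
  )
}

#' Tidy an embedding matrix
#'
#' @param x An `embedding_matrix`.
#' @param ... Unused.
#' @return Tibble with `node_id` and one `d<i>` column per dimension.
#' @exportS3Method generics::tidy
tidy.embedding_matrix <- function(x, ...) {
  m <- as.matrix(x)
  colnames(m) <- paste0("d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(node_id = rownames(x)), tibble::as_tibble(m))
}

#' Summary of a filtered split
#'
#' @param x A `filtered_split`.
#' @param ... Unused.
#' @return One-row tibble with member sizes and false-negative rates.
#' @exportS3Method generics::glance
glance.filtered_split <- function(x, ...) {
  tibble::tibble(
    target_edge_type = x$target_edge_type,
    unbiased = x$unbiased,
    n_train_positive = nrow(x$train_positive),
    n_test_positive = nrow(x$test_positive),
    n_train_negative = nrow(x$train_negative),
    n_test_negative = nrow(x$test_negative),
    fn_train_pct = x$fn_train,
    fn_test_pct = x$fn_test
  )
}

#' Plot per-holdout metrics of a task result
#'
#' Bar chart of balanced accuracy per holdout with the mean as a horizontal
#' line.
#'
#' @param object A `task_result`.
#' @param metric Metric column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.task_result <- function(object, metric = "balanced_accuracy", ...) {
  df <- object$results
  stopifnot(metric %in% names(df))
  m <- mean(df[[metric]])
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$holdout),
    y = .data[[metric]]
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = m, linetype = 2) +
    ggplot2::labs(
      x = "holdout", y = metric,
      title = object$task,
      subtitle = sprintf("mean %s = %.3f", metric, m)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 2D projection of an embedding
#'
#' Projects the embedding with [project_2d()] (unless it is already
#' two-dimensional) and scatters the nodes, coloured by node type when a
#' graph is supplied.
#'
#' @param object An `embedding_matrix`.
#' @param graph Optional [knowledge_graph] supplying node types for colour.
#' @param seed Seed for the projection.
#' @param ... Passed to [project_2d()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.embedding_matrix <- function(object, graph = NULL, seed = 1L, ...) {
  Y <- if (ncol(object) == 2) as.matrix(object) else project_2d(object, seed = seed, ...)
  df <- tibble::tibble(node_id = rownames(object), x = Y[, 1], y = Y[, 2])
  if (!is.null(graph)) {
    df <- dplyr::left_join(df, graph$nodes, by = "node_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$node_type))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
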