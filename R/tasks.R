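#' Classifier specification with hyperparameter grid
#'
#' Describes the downstream classifier: a decision tree (rpart) or random
#' forest (ranger), a hyperparameter grid searched by internal stratified
#' cross-validation on balanced accuracy, and a seed. Ties in the grid search
#' are broken by the first-listed grid entry.
#'
#' Default grids: decision tree `max_depth` {5, 10, 20, NA} x `min_leaf`
#' {1, 5, 20}; random forest `trees` {100, 300} x `max_depth` {10, NA} x
#' `min_leaf` {1, 5} (`NA` = unlimited depth).
#'
#' @param family `"decision_tree"` or `"random_forest"`.
#' @param grid Data frame of hyperparameter combinations; `NULL` for the
#'   default grid.
#' @param inner_cv_folds Folds for the internal grid-search CV.
#' @param seed Integer seed.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "decision_tree"),
                            grid = NULL, inner_cv_folds = 3, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "decision_tree") {
      expand.grid(max_depth = c(5, 10, 20, NA), min_leaf = c(1, 5, 20))
    } else {
      expand.grid(trees = c(100, 300), max_depth = c(10, NA), min_leaf = c(1, 5))
    }
  }
  if (nrow(grid) == 0) stop("hyperparameter grid must be non-empty", call. = FALSE)
  structure(
    list(
      family = family, grid = tibble::as_tibble(grid),
      inner_cv_folds = as.integer(inner_cv_folds), seed = as.integer(seed)
    ),
    class = "classifier_spec"
  )
}

fit_one <- function(features, labels, family, hp, seed) {
  df <- as.data.frame(features)
  df$.y <- labels
  if (family == "decision_tree") {
    local_seed(seed)
    rpart::rpart(
      .y ~ ., df,
      method = "class",
      control = rpart::rpart.control(
        maxdepth = if (is.na(hp$max_depth)) 30 else hp$max_depth,
        minbucket = hp$min_leaf, minsplit = max(2, 2 * hp$min_leaf),
        cp = 0, xval = 0
      )
    )
  } else {
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = hp$trees,
      max.depth = if (is.na(hp$max_depth)) 0 else hp$max_depth,
      min.node.size = hp$min_leaf,
      classification = TRUE, seed = seed, num.threads = 1,
      verbose = FALSE
    )
  }
}

predict_one <- function(model, features) {
  df <- as.data.frame(features)
  if (inherits(model, "rpart")) {
    factor(predict(model, df, type = "class"), levels = attr(model, "ylevels"))
  } else {
    predict(model, df, num.threads = 1, verbose = FALSE)$predictions
  }
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit a classifier with internal grid search
#'
#' Runs stratified `inner_cv_folds`-fold cross-validation over the grid,
#' selects the combination maximising mean balanced accuracy (first-listed
#' entry on ties), and refits it on the full training data. Deterministic
#' given the spec's seed.
#'
#' @param features Numeric feature matrix.
#' @param labels Factor (or coercible) class labels; at least 2 classes.
#' @param spec A [classifier_spec()].
#' @return Object of class `classifier_fit`: `model`, `family`,
#'   `best_params`, `cv_results` (tibble of mean CV balanced accuracy per
#'   grid row). Use [predict_classes()] on new features.
#' @export
fit_classifier <- function(features, labels, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes in labels", call. = FALSE)
  local_seed(spec$seed)
  grid <- spec$grid

  cv_ba <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    fold <- stratified_folds(labels, spec$inner_cv_folds)
    for (gi in seq_len(nrow(grid))) {
      bas <- vapply(seq_len(spec$inner_cv_folds), function(f) {
        tr <- fold != f
        if (nlevels(droplevels(labels[tr])) < 2 || !any(!tr)) {
          return(NA_real_)
        }
        model <- fit_one(features[tr, , drop = FALSE], labels[tr], spec$family,
          grid[gi, ],
          seed = spec$seed + gi
        )
        pred <- predict_one(model, features[!tr, , drop = FALSE])
        suppressWarnings(balanced_accuracy(confusion_table(
          labels[!tr], pred,
          levels = levels(labels)
        )))
      }, numeric(1))
      cv_ba[gi] <- mean(bas, na.rm = TRUE)
    }
    best <- which.max(cv_ba) # which.max takes the first maximum: tie rule
  } else {
    best <- 1L
  }
  model <- fit_one(features, labels, spec$family, grid[best, ], seed = spec$seed)
  structure(
    list(
      model = model, family = spec$family, best_params = grid[best, ],
      cv_results = dplyr::bind_cols(grid, cv_balanced_accuracy = cv_ba),
      levels = levels(labels)
    ),
    class = "classifier_fit"
  )
}

#' @rdname fit_classifier
#' @param fit A `classifier_fit`.
#' @export
predict_classes <- function(fit, features) {
  factor(as.character(predict_one(fit$model, features)), levels = fit$levels)
}

#' Edge feature construction by endpoint concatenation
#'
#' The feature vector of an edge \{u, v\} is the concatenation of the two
#' endpoint embeddings in canonical order (smaller dense index first), so it
#' is independent of the orientation in which the edge is supplied. Width is
#' always `2 * dim`.
#'
#' @param emb An `embedding_matrix` (rows aligned to the graph's dense
#'   index, row names = node ids).
#' @param edges Data frame with dense-index columns `from`, `to`, or id
#'   columns `source`, `target`.
#' @return Numeric matrix `nrow(edges) x 2*ncol(emb)`.
#' @export
edge_features <- function(emb, edges) {
  ed <- as.data.frame(edges)
  if (all(c("from", "to") %in% names(ed))) {
    fr <- ed$from
    to <- ed$to
  } else {
    fr <- match(as.character(ed$source), rownames(emb))
    to <- match(as.character(ed$target), rownames(emb))
  }
  bad <- which(is.na(fr) | is.na(to) | fr < 1 | to < 1 | fr > nrow(emb) | to > nrow(emb))
  if (length(bad) > 0) {
    stop(sprintf("edge %d references an endpoint missing from the embedding", bad[1]),
      call. = FALSE
    )
  }
  a <- pmin(fr, to)
  b <- pmax(fr, to)
  X <- cbind(as.matrix(emb)[a, , drop = FALSE], as.matrix(emb)[b, , drop = FALSE])
  colnames(X) <- c(
    paste0("a_", seq_len(ncol(emb))),
    paste0("b_", seq_len(ncol(emb)))
  )
  rownames(X) <- NULL
  X
}

binary_edge_metrics <- function(truth, pred) {
  ct <- confusion_table(truth, pred, levels = c("negative", "positive"))
  f1 <- suppressWarnings(f1_scores(ct))
  rec <- diag(as.matrix(ct)) / pmax(rowSums(ct), 1)
  tibble::tibble(
    balanced_accuracy = suppressWarnings(balanced_accuracy(ct)),
    accuracy_positive = rec[["positive"]],
    accuracy_negative = rec[["negative"]],
    f1_macro = f1$macro_f1,
    f1_weighted = f1$weighted_f1
  )
}

new_task_result <- function(task, results, provenance) {
  metrics <- setdiff(names(results), c("holdout", "recalls"))
  summary <- tidyr::pivot_longer(
    results[, c("holdout", metrics)], -"holdout",
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
    )
  structure(
    list(task = task, results = results, summary = summary, provenance = provenance),
    class = "task_result"
  )
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s over %d holdouts\n", x$task, nrow(x$results)))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Node-type prediction task
#'
#' Restricts the graph to the `top_k` most frequent node types (ties broken
#' lexicographically), then runs repeated stratified 70:30-style holdouts
#' over those nodes: per holdout the classifier is grid-searched by internal
#' CV on the training embeddings, refitted, and evaluated on the held-out
#' nodes. The embedding must have been computed on the full graph — node-type
#' prediction removes no edges.
#'
#' @param g A [knowledge_graph].
#' @param emb An `embedding_matrix` of `g` (or any feature matrix row-aligned
#'   to the dense index, e.g. a 2-column [project_2d()] output).
#' @param top_k How many of the most frequent node types to classify.
#' @param spec A [classifier_spec()].
#' @param n_holdouts,test_fraction Holdout scheme.
#' @param seed Integer seed.
#' @return A `task_result` with per-holdout balanced accuracy, macro and
#'   weighted F1, and per-class recall (list column `recalls`).
#' @export
run_node_type_prediction <- function(g, emb, top_k, spec = classifier_spec(),
                                     n_holdouts = 5, test_fraction = 0.3, seed = 1L) {
  freq <- dplyr::count(g$nodes, .data$node_type)
  if (top_k > nrow(freq)) stop("top_k exceeds the number of node types", call. = FALSE)
  keep_types <- dplyr::arrange(freq, dplyr::desc(.data$n), .data$node_type)$node_type[seq_len(top_k)]
  sel <- which(g$nodes$node_type %in% keep_types)
  labels <- factor(g$nodes$node_type[sel], levels = sort(keep_types))
  X <- as.matrix(emb)[sel, , drop = FALSE]

  folds <- stratified_label_holdout(
    seq_along(sel), as.character(labels), test_fraction, n_holdouts, seed
  )
  results <- purrr::map_dfr(seq_len(n_holdouts), function(h) {
    fh <- folds[folds$holdout == h, ]
    tr <- as.integer(fh$node_id[fh$set == "train"])
    te <- as.integer(fh$node_id[fh$set == "test"])
    if (dplyr::n_distinct(labels[te]) < length(keep_types)) {
      stop("a selected type has no test members in holdout ", h, call. = FALSE)
    }
    spec_h <- spec
    spec_h$seed <- spec$seed + h
    fit <- fit_classifier(X[tr, , drop = FALSE], labels[tr], spec_h)
    pred <- predict_classes(fit, X[te, , drop = FALSE])
    ct <- confusion_table(labels[te], pred, levels = levels(labels))
    f1 <- suppressWarnings(f1_scores(ct))
    tibble::tibble(
      holdout = h,
      balanced_accuracy = suppressWarnings(balanced_accuracy(ct)),
      f1_macro = f1$macro_f1,
      f1_weighted = f1$weighted_f1,
      recalls = list(f1$per_class[, c("class", "recall")])
    )
  })
  new_task_result(
    "node_type_prediction", results,
    list(
      top_k = top_k, types = keep_types, classifier = spec,
      embedding = attr(emb, "params"), seed = seed,
      n_holdouts = n_holdouts, test_fraction = test_fraction
    )
  )
}

#' Generic-edge prediction task
#'
#' Per holdout: split the edges with [connected_holdout()] (component count
#' preserved), embed the *training* graph, sample degree-aware negatives for
#' train and test against the full edge set (mutually disjoint, matching the
#' positive proportions), featurise edges by endpoint concatenation, fit the
#' classifier on the training edges, and evaluate on the held-out positive
#' and negative edges. Negatives are not endpoint-type-constrained by
#' default: the generic task is type-agnostic.
#'
#' @param g A [knowledge_graph].
#' @param embed_params [node2vec_params()] or [line_params()]; the seed is
#'   re-derived per holdout.
#' @param spec A [classifier_spec()].
#' @param n_holdouts,test_fraction,negative_ratio Protocol controls.
#' @param seed Integer seed.
#' @param type_constrained Restrict negative endpoint types (default FALSE).
#' @return A `task_result` with balanced accuracy, per-class accuracy and F1
#'   per holdout.
#' @export
run_generic_edge_prediction <- function(g, embed_params, spec = classifier_spec(),
                                        n_holdouts = 5, test_fraction = 0.3,
                                        negative_ratio = 1, seed = 1L,
                                        type_constrained = FALSE) {
  type_pairs <- if (type_constrained) edge_type_endpoint_pairs(g, g$edges) else NULL
  results <- purrr::map_dfr(seq_len(n_holdouts), function(h) {
    seed_h <- seed + 1000L * (h - 1L)
    split <- connected_holdout(g, test_fraction, seed_h)
    ep <- embed_params
    ep$seed <- seed_h
    emb <- embed_graph(training_graph(g, split), ep)

    n_tr <- nrow(split$train_pairs)
    n_te <- nrow(split$test_pairs)
    negatives <- sample_negative_edges(
      g, negative_ratio * (n_tr + n_te),
      type_pairs = type_pairs, seed = seed_h + 1L
    )
    local_seed(seed_h + 2L)
    shuf <- negatives[sample.int(nrow(negatives)), ]
    neg_te <- shuf[seq_len(negative_ratio * n_te), , drop = FALSE]
    neg_tr <- shuf[-seq_len(negative_ratio * n_te), , drop = FALSE]

    tr_pairs <- as.data.frame(split$train_pairs)
    te_pairs <- as.data.frame(split$test_pairs)
    Xtr <- rbind(edge_features(emb, tr_pairs), edge_features(emb, neg_tr))
    ytr <- factor(
      rep(c("positive", "negative"), c(n_tr, nrow(neg_tr))),
      levels = c("negative", "positive")
    )
    Xte <- rbind(edge_features(emb, te_pairs), edge_features(emb, neg_te))
    yte <- factor(
      rep(c("positive", "negative"), c(n_te, nrow(neg_te))),
      levels = c("negative", "positive")
    )
    spec_h <- spec
    spec_h$seed <- spec$seed + h
    fit <- fit_classifier(Xtr, ytr, spec_h)
    pred <- predict_classes(fit, Xte)
    dplyr::bind_cols(tibble::tibble(holdout = h), binary_edge_metrics(yte, pred))
  })
  new_task_result(
    "generic_edge_prediction", results,
    list(
      embedding = embed_params, classifier = spec, seed = seed,
      n_holdouts = n_holdouts, test_fraction = test_fraction,
      negative_ratio = negative_ratio
    )
  )
}

#' Specific-edge prediction task
#'
#' Per holdout: build a `filtered_split` for the target edge type with the
#' unbiased (default) or biased pipeline, embed the training graph, fit the
#' classifier on the filtered positive/negative training edges, and evaluate
#' on the filtered test edges. Reports balanced accuracy, accuracy on
#' positives/negatives (per-class recall), F1, weighted F1 and the measured
#' false-negative percentage of the negative test set.
#'
#' @inheritParams run_generic_edge_prediction
#' @param target_edge_type Edge type to predict.
#' @param unbiased Use the leakage-free pipeline (`TRUE`) or the biased
#'   baseline (`FALSE`).
#' @param type_constrained Restrict negative endpoint types (default TRUE).
#' @return A `task_result`; its per-holdout tibble includes `fn_pct`.
#' @export
run_specific_edge_prediction <- function(g, target_edge_type, embed_params,
                                         spec = classifier_spec("decision_tree"),
                                         n_holdouts = 5, test_fraction = 0.3,
                                         negative_ratio = 1, seed = 1L,
                                         unbiased = TRUE, type_constrained = TRUE) {
  results <- purrr::map_dfr(seq_len(n_holdouts), function(h) {
    seed_h <- seed + 1000L * (h - 1L)
    splitter <- if (unbiased) unbiased_specific_edge_split else biased_specific_edge_split
    fs <- splitter(
      g, target_edge_type, test_fraction, negative_ratio, seed_h,
      type_constrained = type_constrained
    )
    ep <- embed_params
    ep$seed <- seed_h
    emb <- embed_graph(fs$training_graph, ep)

    Xtr <- rbind(
      edge_features(emb, fs$train_positive),
      edge_features(emb, fs$train_negative)
    )
    ytr <- factor(
      rep(c("positive", "negative"), c(nrow(fs$train_positive), nrow(fs$train_negative))),
      levels = c("negative", "positive")
    )
    Xte <- rbind(
      edge_features(emb, fs$test_positive),
      edge_features(emb, fs$test_negative)
    )
    yte <- factor(
      rep(c("positive", "negative"), c(nrow(fs$test_positive), nrow(fs$test_negative))),
      levels = c("negative", "positive")
    )
    spec_h <- spec
    spec_h$seed <- spec$seed + h
    fit <- fit_classifier(Xtr, ytr, spec_h)
    pred <- predict_classes(fit, Xte)
    dplyr::bind_cols(
      tibble::tibble(holdout = h),
      binary_edge_metrics(yte, pred),
      tibble::tibble(fn_pct = fs$fn_test)
    )
  })
  new_task_result(
    "specific_edge_prediction", results,
    list(
      target_edge_type = target_edge_type, unbiased = unbiased,
      embedding = embed_params, classifier = spec, seed = seed,
      n_holdouts = n_holdouts, test_fraction = test_fraction,
      negative_ratio = negative_ratio
    )
  )
}
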