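#' Project an embedding to two dimensions (t-SNE)
#'
#' Reporting utility: computes an exact t-SNE projection of the embedding for
#' visual inspection and for the low-dimensional-feature comparison in the
#' node-type task. The implementation is the canonical exact algorithm —
#' per-point Gaussian bandwidths calibrated to the target perplexity by
#' bisection, symmetrised affinities with early exaggeration, Student-t
#' low-dimensional kernel, momentum gradient descent — and is quadratic in
#' the number of rows, intended for desk-scale inputs (a few thousand rows).
#'
#' @param emb An `embedding_matrix` or numeric matrix with at least 3 rows
#'   and at least 2 columns.
#' @param seed Integer seed for the random initialisation.
#' @param perplexity Target perplexity (effective neighbourhood size);
#'   reduced automatically if the input is too small.
#' @param max_iter Gradient-descent iterations.
#' @return Numeric matrix with `nrow(emb)` rows and 2 columns (finite
#'   coordinates), row names preserved.
#' @export
project_2d <- function(emb, seed = 1L, perplexity = 30, max_iter = 300) {
  X <- as.matrix(emb)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows to project", call. = FALSE)
  if (ncol(X) < 2) stop("need at least 2 input dimensions", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)
  local_seed(as.integer(seed))

  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  diag(D2) <- Inf
  logU <- log(perplexity)

  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0
    hi <- Inf
    beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        H <- 0
      } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { # too flat -> narrow kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    w <- exp(-di * beta)
    sw <- sum(w)
    pi <- if (sw < 1e-300) rep(1 / (n - 1), n - 1) else w / sw
    P[i, -i] <- pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  eta <- max(50, n / 12)
  exaggeration <- 12
  stop_exagg <- min(100, floor(max_iter / 3))

  for (it in seq_len(max_iter)) {
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    Pe <- if (it <= stop_exagg) P * exaggeration else P
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it <= 20) 0.5 else 0.8
    dY <- momentum * dY - eta * grad
    Y <- dY + Y
    Y <- sweep(Y, 2, colMeans(Y))
  }
  if (any(!is.finite(Y))) stop("projection diverged to non-finite coordinates", call. = FALSE)
  rownames(Y) <- rownames(emb)
  colnames(Y) <- c("x", "y")
  Y
}
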