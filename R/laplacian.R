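# Laplacian score: features that vary little across neighbouring samples,
# relative to their overall variance, carry the local geometry of the data.

#' Laplacian score feature selection
#'
#' Builds a symmetric (union) binary k-nearest-neighbour graph over the
#' samples — binary edge weights correspond to the heat-kernel similarity in
#' the limit of a large bandwidth — and scores each feature f by
#' \deqn{LS(f) = \frac{\tilde f^\top L \tilde f}{\tilde f^\top D \tilde f}}
#' where `L = D - W` is the graph Laplacian, `D` the degree matrix and
#' \eqn{\tilde f} the feature after removing its degree-weighted mean. Lower
#' scores mark more relevant features; the `nBest` smallest are selected.
#' Stored scores are negated so that the package-wide orientation "larger =
#' more selected" holds.
#'
#' Constant features have an undefined (0/0) score; they receive the worst
#' possible score and are never selected.
#'
#' @param x a [RecordMatrix-class] or a samples-by-features binary matrix.
#' @param nBest number of features to select (default 100).
#' @param kNeighbors neighbours in the sample graph (default 5).
#' @param ... unused.
#' @return a [SelectionResult-class] with `method = "ls"`.
#' @export
setMethod("laplacianScore", "ANY",
  function(x, nBest = 100L, kNeighbors = 5L, ...) {
    X <- .sampleMatrix(x)
    p <- ncol(X)
    stopifnot(nBest >= 1L, nBest <= p)
    W <- .knnGraph(X, kNeighbors)
    d <- rowSums(W)
    ls <- numeric(p)
    for (j in seq_len(p)) {
      f <- X[, j]
      ft <- f - sum(f * d) / sum(d)
      den <- sum(ft^2 * d)
      if (den < 1e-12) {
        ls[j] <- Inf
        next
      }
      num <- sum(ft * (d * ft - W %*% ft))
      ls[j] <- num / den
    }
    if (any(is.infinite(ls)))
      warning(sum(is.infinite(ls)),
              " constant feature(s) received the worst score", call. = FALSE)
    scores <- -ls
    selected <- .topN(scores, nBest)
    .selectionResult("ls", scores, selected, .featureCodesOf(x, p), nBest,
                     details = list(config = list(k_neighbors = kNeighbors)))
  })
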