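# Principal feature analysis: cluster the PCA loading rows of the features
# and keep, per cluster, the feature closest to the centroid.

# Exact PCA computed incrementally: mean and cross-product accumulated over
# row batches (memory bounded by batchSize rows), then an eigendecomposition
# of the resulting covariance. Returns the loading matrix V (features x
# components).
.batchedPcaLoadings <- function(X, nComponents, batchSize) {
  n <- nrow(X)
  p <- ncol(X)
  sumX <- numeric(p)
  cross <- matrix(0, p, p)
  for (start in seq(1L, n, by = batchSize)) {
    B <- X[start:min(start + batchSize - 1L, n), , drop = FALSE]
    sumX <- sumX + colSums(B)
    cross <- cross + crossprod(B)
  }
  mu <- sumX / n
  cov <- (cross - n * tcrossprod(mu)) / (n - 1)
  eg <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  eg$vectors[, seq_len(nComponents), drop = FALSE]
}

#' Principal feature analysis (PFA)
#'
#' Represents every feature by its row of PCA loadings over the leading
#' `nComponents` principal components (PCA is computed exactly but in row
#' batches of `batchSize`, so memory stays bounded on tall matrices), runs
#' k-means with `nBest` clusters on these rows, and selects in each cluster
#' the feature whose loading row lies nearest (Euclidean) to the centroid.
#' Ties break to the lowest feature index. Empty-cluster k-means fits are
#' retried with fresh seeded starts a bounded number of times.
#'
#' @param x a [RecordMatrix-class] or samples-by-features matrix.
#' @param nBest number of features (= clusters) to select (default 100).
#' @param nComponents retained components; default `ceiling(p/2)`.
#' @param batchSize rows per PCA batch; default `2 * p`.
#' @param seed integer seed for k-means.
#' @param ... unused.
#' @return a [SelectionResult-class] with `method = "pfa"`. Scores are the
#'   negated distance of each feature's loading row to its cluster centroid
#'   (a within-cluster typicality, not a global ranking).
#' @export
setMethod("pfaSelect", "ANY",
  function(x, nBest = 100L, nComponents = NULL, batchSize = NULL,
           seed = 1L, ...) {
    X <- .sampleMatrix(x)
    p <- ncol(X)
    stopifnot(nBest >= 1L, nBest <= p)
    if (is.null(nComponents)) nComponents <- ceiling(p / 2)
    stopifnot(nComponents >= 1L, nComponents <= p)
    if (is.null(batchSize)) batchSize <- 2L * p
    V <- .batchedPcaLoadings(X, nComponents, batchSize)
    codes <- .featureCodesOf(x, p)
    if (nBest == p) {
      return(.selectionResult("pfa", rep(0, p), seq_len(p), codes, nBest,
                              details = list(config = list(
                                n_components = nComponents,
                                batch_size = batchSize, seed = seed))))
    }
    km <- NULL
    for (attempt in 0:4) {
      km <- withSeed(seed + attempt, tryCatch(
        stats::kmeans(V, centers = nBest, iter.max = 100L, nstart = 1L),
        error = function(e) NULL))
      if (!is.null(km) && all(km$size > 0)) break
      km <- NULL
    }
    if (is.null(km))
      stop("k-means produced empty clusters after bounded retries",
           call. = FALSE)
    dist2centroid <- sqrt(rowSums((V - km$centers[km$cluster, ,
                                                 drop = FALSE])^2))
    selected <- vapply(seq_len(nBest), function(cl) {
      members <- which(km$cluster == cl)
      members[order(dist2centroid[members], members)[1L]]
    }, integer(1))
    selected <- sort(selected)
    .selectionResult("pfa", -dist2centroid, selected, codes, nBest,
                     details = list(config = list(
                       n_components = nComponents,
                       batch_size = batchSize, seed = seed)))
  })
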