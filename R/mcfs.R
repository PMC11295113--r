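# Multi-cluster feature selection: spectral embedding of the sample graph,
# then one L1-regularized regression of each embedding direction on the
# features; a feature's score is its largest absolute coefficient.

# Spectral embedding: generalized eigenproblem L y = lambda D y solved via
# the symmetric normalized Laplacian. Returns the nEig eigenvectors of
# smallest eigenvalue after dropping the trivial (constant-like) one,
# normalized to unit length.
.spectralEmbedding <- function(W, nEig) {
  d <- rowSums(W)
  if (any(d == 0))
    stop("degenerate graph (isolated node); increase k_neighbors",
         call. = FALSE)
  dis <- 1 / sqrt(d)
  M <- diag(nrow(W)) - (dis * W) * rep(dis, each = nrow(W))
  M <- (M + t(M)) / 2
  eg <- tryCatch(eigen(M, symmetric = TRUE), error = function(e) {
    stop("eigen-decomposition failed (", conditionMessage(e),
         "); increase k_neighbors", call. = FALSE)
  })
  n <- nrow(W)
  cols <- seq.int(n - 1L, by = -1L, length.out = nEig)
  Y <- dis * eg$vectors[, cols, drop = FALSE]
  sweep(Y, 2L, sqrt(colSums(Y^2)), `/`)
}

# Exact lasso homotopy (LARS with the lasso modification) for
#   min 1/(2n) ||y - X b||^2 + lambda ||b||_1
# on column-centered data, stopped at the path point where the active set
# would exceed `maxActive` features. Exact breakpoints make the solution
# reproducible and keep exact duplicate columns from splitting a
# coefficient: the first duplicate to enter stays, later ones are tied to
# the boundary forever and never enter.
.lassoLars <- function(X, y, maxActive) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  cvec <- as.numeric(crossprod(Xc, yc)) / n
  lambda <- max(abs(cvec))
  beta <- numeric(p)
  A <- integer(0)
  s <- numeric(0)
  excluded <- rep(FALSE, p)
  tol <- 1e-10
  G <- crossprod(Xc) / n
  for (iter in seq_len(10L * p + 10L)) {
    if (lambda <= tol) break
    if (!length(A)) {
      j <- which.max(abs(cvec) * !excluded)
      A <- j
      s <- sign(cvec[j])
    }
    dA <- tryCatch(solve(G[A, A, drop = FALSE], s), error = function(e) NULL)
    if (is.null(dA)) break
    v <- as.numeric(G[, A, drop = FALSE] %*% dA)
    inA <- seq_len(p) %in% A
    # entry candidates: inactive feature correlations catch the boundary
    gammaIn <- rep(Inf, p)
    for (j in which(!inA & !excluded)) {
      g1 <- (lambda - cvec[j]) / (1 - v[j])
      g2 <- (lambda + cvec[j]) / (1 + v[j])
      cand <- c(if (is.finite(g1) && g1 > tol) g1,
                if (is.finite(g2) && g2 > tol) g2)
      if (length(cand)) gammaIn[j] <- min(cand)
    }
    # drop candidates: an active coefficient crosses zero
    gammaOut <- rep(Inf, length(A))
    cross <- -beta[A] / dA
    gammaOut[cross > tol] <- cross[cross > tol]
    gIn <- min(gammaIn)
    gOut <- min(gammaOut)
    evt <- if (gOut <= gIn && gOut <= lambda) "drop"
           else if (gIn <= lambda) "enter"
           else "end"
    gamma <- min(gIn, gOut, lambda)
    beta[A] <- beta[A] + gamma * dA
    cvec <- cvec - gamma * v
    lambda <- lambda - gamma
    if (evt == "drop") {
      k <- A[which.min(gammaOut)]
      beta[k] <- 0
      s <- s[A != k]
      A <- A[A != k]
    } else if (evt == "enter") {
      j <- which.min(gammaIn)
      # a feature collinear with the active set can never enter
      GA <- G[c(A, j), c(A, j), drop = FALSE]
      if (rcond(GA) < 1e-10) {
        excluded[j] <- TRUE
        next
      }
      if (length(A) >= maxActive) break
      A <- c(A, j)
      s <- c(s, sign(cvec[j]))
    } else {
      break
    }
  }
  list(coef = beta, lambda = lambda)
}

# L1 path of one embedding direction on the features; returns the
# coefficients at the path point where the active set reaches `budget`
# nonzeros (or the path end), together with that penalty value.
.mcfsPathCoef <- function(X, y, budget) {
  .lassoLars(X, y, budget)
}

#' Multi-cluster feature selection (MCFS)
#'
#' Builds the same 5-nearest-neighbour binary sample graph as the Laplacian
#' score, solves the generalized eigenproblem \eqn{L y = \lambda D y} for the
#' `nEigvecs` eigenvectors of smallest eigenvalue (excluding the trivial
#' constant direction), regresses each eigenvector on the feature columns
#' with an L1 penalty capped at `l1Budget` active features, and scores every
#' feature by the maximum absolute coefficient it attains across
#' eigenvectors. The `nBest` largest scores are selected.
#'
#' @param x a [RecordMatrix-class] or samples-by-features matrix.
#' @param nBest number of features to select (default 100).
#' @param kNeighbors neighbours in the sample graph (default 5).
#' @param nEigvecs number of non-trivial eigenvectors (default 5).
#' @param l1Budget cardinality cap of each L1 path (default `nBest`).
#' @param ... unused.
#' @return a [SelectionResult-class] with `method = "mcfs"`.
#' @export
setMethod("mcfsScores", "ANY",
  function(x, nBest = 100L, kNeighbors = 5L, nEigvecs = 5L,
           l1Budget = nBest, ...) {
    X <- .sampleMatrix(x)
    n <- nrow(X)
    p <- ncol(X)
    stopifnot(nBest >= 1L, nBest <= p, nEigvecs >= 1L, nEigvecs < n)
    W <- .knnGraph(X, kNeighbors)
    Y <- .spectralEmbedding(W, nEigvecs)
    scores <- rep(0, p)
    for (k in seq_len(ncol(Y))) {
      coefs <- .mcfsPathCoef(X, Y[, k], l1Budget)$coef
      scores <- pmax(scores, abs(coefs))
    }
    selected <- .topN(scores, nBest)
    .selectionResult("mcfs", scores, selected, .featureCodesOf(x, p), nBest,
                     details = list(config = list(
                       k_neighbors = kNeighbors, n_eigvecs = nEigvecs,
                       l1_budget = l1Budget)))
  })
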