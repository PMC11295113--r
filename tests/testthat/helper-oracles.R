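# Independent reference implementations used as oracles. They share no code
# with the package internals they check.

# Brute-force Laplacian score: explicit W, D, L matrices and quadratic forms.
denseLaplacianOracle <- function(X, k) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D2[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])
    nb <- nb[nb != i][seq_len(k)]
    W[i, nb] <- 1
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  Dg <- diag(rowSums(W))
  L <- Dg - W
  one <- rep(1, n)
  apply(X, 2L, function(f) {
    ft <- f - as.numeric((t(f) %*% Dg %*% one) / (t(one) %*% Dg %*% one)) * one
    den <- as.numeric(t(ft) %*% Dg %*% ft)
    if (den < 1e-12) return(Inf)
    as.numeric(t(ft) %*% L %*% ft) / den
  })
}

# Exact lasso solution of min 1/(2n)||y - X b||^2 + lambda ||b||_1 at a given
# lambda, by exhaustive enumeration of active sets (up to maxSupport) and
# sign patterns, keeping the candidate that satisfies the KKT conditions.
lassoKktOracle <- function(X, y, lambda, maxSupport, tol = 1e-6) {
  n <- nrow(X)
  p <- ncol(X)
  # empty support first
  if (max(abs(crossprod(X, y) / n)) <= lambda + tol) return(numeric(p))
  for (size in seq_len(maxSupport)) {
    for (S in utils::combn(p, size, simplify = FALSE)) {
      XS <- X[, S, drop = FALSE]
      G <- crossprod(XS) / n
      if (abs(det(G)) < 1e-12) next
      signGrid <- as.matrix(expand.grid(rep(list(c(-1, 1)), size)))
      for (r in seq_len(nrow(signGrid))) {
        s <- signGrid[r, ]
        b <- solve(G, crossprod(XS, y) / n - lambda * s)
        if (any(sign(b) != s)) next
        resid <- y - XS %*% b
        grad <- crossprod(X, resid) / n
        if (any(abs(grad[S] - lambda * s) > tol)) next
        if (any(abs(grad[-S]) > lambda + tol)) next
        out <- numeric(p)
        out[S] <- b
        return(out)
      }
    }
  }
  stop("KKT oracle found no solution")
}

# Paired-bootstrap reference for the DeLong comparison: resample rows,
# recompute both AUCs, normal p-value from the bootstrap SE of the
# difference.
rankAuc <- function(scores, labels) {
  pos <- which(labels == 1)
  r <- rank(scores)
  (sum(r[pos]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * (length(labels) - length(pos)))
}

bootstrapDelongOracle <- function(scoresA, scoresB, labels, B = 10000,
                                  seed = 42) {
  set.seed(seed)
  n <- length(labels)
  d0 <- rankAuc(scoresA, labels) - rankAuc(scoresB, labels)
  diffs <- numeric(B)
  b <- 0L
  while (b < B) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) next
    b <- b + 1L
    diffs[b] <- rankAuc(scoresA[idx], labels[idx]) -
      rankAuc(scoresB[idx], labels[idx])
  }
  z <- d0 / stats::sd(diffs)
  2 * stats::pnorm(-abs(z))
}

# Closed-form two-sided tests.
pairedTOracle <- function(a, b) {
  d <- a - b
  tval <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  2 * stats::pt(-abs(tval), length(d) - 1)
}

welchOracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tval <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tval), df)
}
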