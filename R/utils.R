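# Small shared helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-stage seed from a master seed and a stage name; kept
# below 2^31 so it is a valid R integer.
.deriveSeed <- function(masterSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(masterSeed) * 7919 + h) %% 2147483587)
}

# Coerce selector input to a dense samples-x-features numeric matrix.
.sampleMatrix <- function(x) {
  if (methods::is(x, "RecordMatrix")) {
    m <- as.matrix(onehot(x))
  } else if (methods::is(x, "Matrix")) {
    m <- as.matrix(x)
  } else {
    m <- as.matrix(x)
  }
  storage.mode(m) <- "double"
  m
}

.featureCodesOf <- function(x, p) {
  if (methods::is(x, "RecordMatrix")) return(featureCodes(x))
  cn <- colnames(x)
  if (is.null(cn)) paste0("F", seq_len(p)) else cn
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.clipProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Elementwise binary cross-entropy (natural log), mean over entries.
.bce <- function(y, p, w = NULL) {
  p <- .clipProb(p)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(w)) return(mean(ll))
  # w: per-column (feature) weights, normalized by their sum
  sum(sweep(ll, 2L, w, `*`)) / (nrow(ll) * sum(w))
}

# Mann-Whitney AUC of scores against binary labels.
.aucMW <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Symmetric (union) binary k-nearest-neighbour graph over the rows of X.
# Returns the adjacency matrix W (0/1, zero diagonal).
.knnGraph <- function(X, k) {
  n <- nrow(X)
  if (k >= n) stop("k_neighbors must be smaller than the number of samples",
                   call. = FALSE)
  d2 <- as.matrix(stats::dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i]
    W[i, ord[seq_len(k)]] <- 1
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}
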