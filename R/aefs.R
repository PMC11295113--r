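# Autoencoder-inspired selection: a single-hidden-layer autoencoder with a
# group-sparsity penalty on the first-layer weight rows; informative inputs
# keep large weight rows.

#' Autoencoder-inspired unsupervised feature selection (AEFS)
#'
#' Trains a one-hidden-layer autoencoder minimizing
#' \deqn{\tfrac{1}{2n}\|X - \hat X\|_F^2
#'   + \alpha \sum_j \|W^{(1)}_{j\cdot}\|_2
#'   + \tfrac{\beta}{2}\sum_l \|W^{(l)}\|_F^2,}
#' the row-wise group penalty (the "L1,2" / group-lasso term) driving whole
#' input rows of the first layer toward zero. A feature's score is the
#' Euclidean norm of its first-layer weight row; the `nBest` largest are
#' selected. Training uses Adam and is deterministic given `seed`.
#'
#' @param x a [RecordMatrix-class] or samples-by-features matrix.
#' @param nBest number of features to select (default 100).
#' @param alpha trade-off of reconstruction vs group sparsity (default 0.001).
#' @param beta weight-decay penalty (default 0.1).
#' @param hiddenUnits hidden width; default `ceiling(p/2)` capped at 256.
#' @param epochs,learningRate,batchSize training budget.
#' @param seed integer seed.
#' @param ... unused.
#' @return a [SelectionResult-class] with `method = "aefs"`.
#' @export
setMethod("aefsSelect", "ANY",
  function(x, nBest = 100L, alpha = 0.001, beta = 0.1,
           hiddenUnits = NULL, epochs = 200L, learningRate = 1e-3,
           batchSize = 64L, seed = 1L, ...) {
    X <- .sampleMatrix(x)
    p <- ncol(X)
    stopifnot(nBest >= 1L, nBest <= p, alpha >= 0, beta >= 0)
    if (is.null(hiddenUnits)) hiddenUnits <- min(256L, ceiling(p / 2))
    fit <- .mlpTrain(X, X, hidden = hiddenUnits, outAct = "identity",
                     loss = "mse", epochs = epochs, lr = learningRate,
                     batchSize = batchSize, l21Alpha = alpha, l2Beta = beta,
                     seed = seed)
    if (!all(is.finite(fit$lossHistory)))
      stop("non-finite loss at epoch ",
           which(!is.finite(fit$lossHistory))[1L],
           " (learning rate ", learningRate, ")", call. = FALSE)
    scores <- sqrt(rowSums(fit$layers[[1L]]$W^2))
    selected <- .topN(scores, nBest)
    .selectionResult("aefs", scores, selected, .featureCodesOf(x, p), nBest,
                     details = list(
                       config = list(alpha = alpha, beta = beta,
                                     hidden_units = hiddenUnits,
                                     epochs = epochs,
                                     learning_rate = learningRate,
                                     batch_size = batchSize, seed = seed),
                       lossHistory = fit$lossHistory,
                       firstLayer = fit$layers[[1L]]$W))
  })
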