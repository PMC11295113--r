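# Concrete autoencoder: a selector layer of nBest neurons, each holding a
# logit vector over the input features, trained end-to-end with a decoder.
# Gumbel-Softmax sampling with an exponentially annealed temperature lets the
# layer explore features early and harden into (near) one-hot choices late.

#' Temperature of the concrete selector layer
#'
#' Exponential annealing schedule
#' \deqn{T(e) = T_{start} (T_{end}/T_{start})^{e/E},}
#' starting at `tempStart` (default 20) and ending at `tempEnd`
#' (default 0.01) after `epochs` epochs.
#'
#' @param epoch epoch index in `[0, epochs]`.
#' @param epochs total number of epochs (default 1000).
#' @param tempStart,tempEnd schedule endpoints; `tempEnd < tempStart`.
#' @return the temperature, a positive real.
#' @examples
#' caeTemperature(0)    # 20
#' caeTemperature(1000) # 0.01
#' @export
caeTemperature <- function(epoch, epochs = 1000L, tempStart = 20,
                           tempEnd = 0.01) {
  stopifnot(tempStart > 0, tempEnd > 0, tempEnd < tempStart)
  if (any(epoch < 0) || any(epoch > epochs))
    stop("epoch must lie in [0, epochs]", call. = FALSE)
  tempStart * (tempEnd / tempStart)^(epoch / epochs)
}

.softmaxRows <- function(A) {
  E <- exp(A - apply(A, 1L, max))
  E / rowSums(E)
}

#' Concrete autoencoder feature selection (CAE / CAEWW)
#'
#' The encoder is a concrete selector layer of `nBest` neurons. During
#' training, neuron `k` outputs \eqn{\sum_j s_{kj} x_j} with
#' \eqn{s_{k\cdot} = \mathrm{softmax}((\mathrm{logits}_{k\cdot} + G)/T)}
#' (Gumbel noise `G`, temperature `T` annealed by [caeTemperature()]). The
#' decoder is a feed-forward network (`decoderHidden` leaky-ReLU layers,
#' sigmoid outputs) trained by binary cross-entropy over all original
#' features. After training each neuron selects its argmax feature (hard
#' selection, no noise); duplicated choices collapse, so fewer than `nBest`
#' distinct features may result.
#'
#' When `featureWeights` is supplied (one weight in (0,1] per feature,
#' typically `depthWeight(depth)` so codes near the tree roots weigh most),
#' each feature's per-element cross-entropy term is multiplied by its weight
#' and the sum normalized by the total weight; this is the weight-adjusted
#' variant (CAEWW), which steers selection toward general codes when
#' descendants are redundant with their ancestors.
#'
#' @param x a [RecordMatrix-class] or samples-by-features binary matrix.
#' @param nBest number of selector neurons (default 100).
#' @param tempStart,tempEnd temperature schedule endpoints (20 and 0.01).
#' @param epochs training epochs (default 1000).
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size (default 64).
#' @param decoderHidden hidden-layer widths of the decoder (default 64, 64).
#' @param featureWeights optional per-feature loss weights in (0,1].
#' @param seed integer seed; the run is fully deterministic given it.
#' @param ... unused.
#' @return a [SelectionResult-class] with `method` `"cae"` or `"caeww"`, the
#'   per-neuron `selectorAssignment`, and the training loss history in
#'   `details`.
#' @export
setMethod("caeSelect", "ANY",
  function(x, nBest = 100L, tempStart = 20, tempEnd = 0.01,
           epochs = 1000L, learningRate = 1e-3, batchSize = 64L,
           decoderHidden = c(64L, 64L), featureWeights = NULL,
           seed = 1L, ...) {
    X <- .sampleMatrix(x)
    n <- nrow(X)
    p <- ncol(X)
    if (nBest > p) stop("nBest exceeds the number of features",
                        call. = FALSE)
    weighted <- !is.null(featureWeights)
    w <- if (weighted) as.numeric(featureWeights) else rep(1, p)
    if (length(w) != p || any(w <= 0) || any(w > 1))
      stop("featureWeights must have one entry in (0,1] per feature",
           call. = FALSE)
    sumw <- sum(w)
    res <- withSeed(seed, {
      logits <- matrix(stats::rnorm(nBest * p, sd = 0.01), nBest, p)
      decoder <- .nnInit(c(nBest, decoderHidden, p))
      decState <- .adamInit(decoder)
      logState <- list(m = logits * 0, v = logits * 0)
      step <- 0L
      lossHistory <- numeric(epochs)
      for (e in seq_len(epochs)) {
        Temp <- caeTemperature(e - 1L, epochs, tempStart, tempEnd)
        perm <- sample.int(n)
        bl <- c()
        for (start in seq(1L, n, by = batchSize)) {
          idx <- perm[start:min(start + batchSize - 1L, n)]
          Xb <- X[idx, , drop = FALSE]
          nb <- length(idx)
          G <- -log(-log(matrix(stats::runif(nBest * p), nBest, p)))
          S <- .softmaxRows((logits + G) / Temp)
          Z <- Xb %*% t(S)
          fwd <- .mlpForward(decoder, Z, "sigmoid")
          P <- .clipProb(fwd$out)
          lval <- sum(sweep(-(Xb * log(P) + (1 - Xb) * log(1 - P)),
                            2L, w, `*`)) / (nb * sumw)
          if (!is.finite(lval))
            stop("non-finite loss at epoch ", e, call. = FALSE)
          dZout <- sweep(fwd$out - Xb, 2L, w, `*`) / (nb * sumw)
          bwd <- .mlpBackward(decoder, fwd, dZout)
          dS <- bwd$dX
          dSel <- crossprod(dS, Xb)          # nBest x p
          dLogits <- S * (dSel - rowSums(dSel * S)) / Temp
          step <- step + 1L
          upd <- .adamStep(decoder, bwd$grads, decState, learningRate, step)
          decoder <- upd$layers
          decState <- upd$state
          logState$m <- 0.9 * logState$m + 0.1 * dLogits
          logState$v <- 0.999 * logState$v + 0.001 * dLogits^2
          logits <- logits - learningRate *
            (logState$m / (1 - 0.9^step)) /
            (sqrt(logState$v / (1 - 0.999^step)) + 1e-8)
          bl <- c(bl, lval)
        }
        lossHistory[e] <- mean(bl)
      }
      list(logits = logits, decoder = decoder, lossHistory = lossHistory)
    })
    assignment <- max.col(res$logits, ties.method = "first")
    selected <- sort(unique(assignment))
    .selectionResult(if (weighted) "caeww" else "cae", NULL, selected,
                     .featureCodesOf(x, p), nBest,
                     selectorAssignment = assignment,
                     details = list(
                       config = list(temp_start = tempStart,
                                     temp_end = tempEnd, epochs = epochs,
                                     learning_rate = learningRate,
                                     batch_size = batchSize,
                                     decoder_hidden = decoderHidden,
                                     weight_adjust = weighted, seed = seed),
                       lossHistory = res$lossHistory,
                       logits = res$logits))
  })

#' Depth-based feature weights for the weight-adjusted CAE
#'
#' Convenience wrapper computing `depthWeight` for every feature of an
#' encoded record matrix.
#'
#' @param x a [RecordMatrix-class].
#' @return numeric weights in (0,1], one per feature.
#' @export
caeFeatureWeights <- function(x) {
  depthWeight(SummarizedExperiment::rowData(x)$depth)
}
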