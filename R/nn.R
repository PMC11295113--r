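# Minimal feed-forward network engine (manual backprop + Adam) shared by the
# autoencoder-based selectors and the reconstruction evaluator. Hidden layers
# use leaky ReLU; the output layer is sigmoid (binary cross-entropy) or
# identity (squared error). Sizes in this package are small enough that base
# R matrix products are the right tool.

.LRELU_SLOPE <- 0.01

.lrelu <- function(z) {
  z * (z > 0) + .LRELU_SLOPE * z * (z <= 0)
}

.lreluGrad <- function(z) {
  (z > 0) + .LRELU_SLOPE * (z <= 0)
}

# Glorot-style initialization; draws from the caller's RNG stream.
.nnInit <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fin <- sizes[l]
    fout <- sizes[l + 1L]
    list(
      W = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / (fin + fout))),
                 fin, fout),
      b = numeric(fout)
    )
  })
}

# Forward pass. dropMasks: NULL or list of per-hidden-layer multiplicative
# masks (inverted dropout, already scaled by 1/keep).
.mlpForward <- function(layers, X, outAct = c("sigmoid", "identity"),
                        dropMasks = NULL) {
  outAct <- match.arg(outAct)
  L <- length(layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    if (l < L) {
      h <- .lrelu(Z[[l]])
      if (!is.null(dropMasks)) h <- h * dropMasks[[l]]
      A[[l + 1L]] <- h
    } else {
      A[[l + 1L]] <- if (outAct == "sigmoid") .sigmoid(Z[[l]]) else Z[[l]]
    }
  }
  list(A = A, Z = Z, out = A[[L + 1L]])
}

# Backward pass from the output pre-activation gradient dZout (n x out).
# Returns per-layer gradients and the gradient with respect to the input.
.mlpBackward <- function(layers, cache, dZout, dropMasks = NULL) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- dZout
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(cache$A[[l]], dZ),
      b = colSums(dZ)
    )
    dA <- dZ %*% t(layers[[l]]$W)
    if (l > 1L) {
      if (!is.null(dropMasks)) dA <- dA * dropMasks[[l - 1L]]
      dZ <- dA * .lreluGrad(cache$Z[[l - 1L]])
    } else {
      dZ <- dA
    }
  }
  list(grads = grads, dX = dZ)
}

.adamInit <- function(layers) {
  lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

.adamStep <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# Generic trainer mapping X -> Y. outWeights: per-output-column loss weights
# for the weighted BCE (normalized by their sum). l21Alpha adds the row-wise
# group penalty on the first layer; l2Beta adds Frobenius weight decay on all
# layers (both enter through the gradient).
.mlpTrain <- function(X, Y, hidden, outAct = "sigmoid", loss = "bce",
                      epochs = 100L, lr = 1e-3, batchSize = 64L,
                      dropout = 0, outWeights = NULL,
                      l21Alpha = 0, l2Beta = 0, seed = 1L) {
  withSeed(seed, {
    n <- nrow(X)
    pOut <- ncol(Y)
    layers <- .nnInit(c(ncol(X), hidden, pOut))
    state <- .adamInit(layers)
    w <- if (is.null(outWeights)) rep(1, pOut) else outWeights
    sumw <- sum(w)
    step <- 0L
    lossHistory <- numeric(epochs)
    keep <- 1 - dropout
    for (e in seq_len(epochs)) {
      perm <- sample.int(n)
      batchLosses <- c()
      for (start in seq(1L, n, by = batchSize)) {
        idx <- perm[start:min(start + batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        masks <- NULL
        if (dropout > 0) {
          masks <- lapply(hidden, function(h) {
            matrix(stats::rbinom(nb * h, 1L, keep) / keep, nb, h)
          })
        }
        fwd <- .mlpForward(layers, Xb, outAct, masks)
        if (loss == "bce") {
          P <- .clipProb(fwd$out)
          lval <- sum(sweep(-(Yb * log(P) + (1 - Yb) * log(1 - P)),
                            2L, w, `*`)) / (nb * sumw)
          dZ <- sweep(fwd$out - Yb, 2L, w, `*`) / (nb * sumw)
        } else {
          R <- fwd$out - Yb
          lval <- sum(R^2) / (2 * nb)
          dZ <- R / nb
        }
        bwd <- .mlpBackward(layers, fwd, dZ, masks)
        grads <- bwd$grads
        if (l21Alpha > 0) {
          W1 <- layers[[1L]]$W
          rn <- sqrt(rowSums(W1^2)) + 1e-8
          grads[[1L]]$W <- grads[[1L]]$W + l21Alpha * W1 / rn
        }
        if (l2Beta > 0) {
          for (l in seq_along(layers))
            grads[[l]]$W <- grads[[l]]$W + l2Beta * layers[[l]]$W
        }
        step <- step + 1L
        upd <- .adamStep(layers, grads, state, lr, step)
        layers <- upd$layers
        state <- upd$state
        batchLosses <- c(batchLosses, lval)
      }
      lossHistory[e] <- mean(batchLosses)
    }
    list(layers = layers, lossHistory = lossHistory)
  })
}

.mlpPredict <- function(layers, X, outAct = "sigmoid") {
  .mlpForward(layers, X, outAct)$out
}
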