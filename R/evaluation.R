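# Reconstruction track: how well do the selected features reconstruct the
# full one-hot feature space, against an input-independent mode baseline?

#' Mode baseline for feature reconstruction
#'
#' Per feature, the majority value in the training rows; exact 50/50 ties
#' break to 0 (absence, the majority regime of sparse code data). For binary
#' cross-entropy, the baseline predicts the (clipped) training frequency as a
#' probability, since a hard 0/1 output has unbounded cross-entropy.
#'
#' @param train a [RecordMatrix-class] or samples-by-features binary matrix.
#' @return list with `mode` (0/1 per feature) and `prob` (training
#'   frequency per feature).
#' @export
modeBaseline <- function(train) {
  X <- .sampleMatrix(train)
  freq <- colMeans(X)
  list(mode = as.numeric(freq > 0.5), prob = freq)
}

#' Train a reconstruction network on a selected feature subset
#'
#' Feed-forward network mapping the selected columns to all original
#' columns: two hidden layers of 64 leaky-ReLU units with 10% dropout, a
#' sigmoid output layer, binary cross-entropy loss, Adam. Deterministic
#' given `seed`.
#'
#' @param train a [RecordMatrix-class] or samples-by-features binary matrix.
#' @param selected non-empty integer vector of feature column indices.
#' @param seed integer seed.
#' @param hidden hidden widths (default 64, 64).
#' @param dropout hidden dropout rate (default 0.1).
#' @param epochs,learningRate,batchSize training budget (defaults 100,
#'   0.001, 64).
#' @return a model handle (list) for [predictReconstruction()].
#' @export
trainReconstructor <- function(train, selected, seed = 1L,
                               hidden = c(64L, 64L), dropout = 0.1,
                               epochs = 100L, learningRate = 1e-3,
                               batchSize = 64L) {
  X <- .sampleMatrix(train)
  selected <- as.integer(selected)
  if (!length(selected)) stop("selected must be non-empty", call. = FALSE)
  stopifnot(all(selected >= 1L), all(selected <= ncol(X)))
  init <- withSeed(seed, .nnInit(c(length(selected), hidden, ncol(X))))
  initialLoss <- .bce(X, .mlpPredict(init, X[, selected, drop = FALSE]))
  fit <- .mlpTrain(X[, selected, drop = FALSE], X, hidden = hidden,
                   outAct = "sigmoid", loss = "bce", epochs = epochs,
                   lr = learningRate, batchSize = batchSize,
                   dropout = dropout, seed = seed)
  structure(list(layers = fit$layers, selected = selected,
                 nFeatures = ncol(X), lossHistory = fit$lossHistory,
                 initialLoss = initialLoss,
                 finalLoss = fit$lossHistory[length(fit$lossHistory)]),
            class = "codesieve_reconstructor")
}

#' Predicted reconstruction probabilities
#'
#' @param model handle from [trainReconstructor()].
#' @param x a [RecordMatrix-class] or samples-by-features matrix with the
#'   same feature space the model was trained on.
#' @return matrix of per-feature probabilities.
#' @export
predictReconstruction <- function(model, x) {
  X <- .sampleMatrix(x)
  stopifnot(ncol(X) == model$nFeatures)
  .mlpPredict(model$layers, X[, model$selected, drop = FALSE])
}

#' Compare reconstruction accuracies with the baseline
#'
#' Two-sided t test across features on (method accuracy - baseline
#' accuracy); paired by default because both are evaluated on the same
#' features, with Welch's unpaired variant behind a flag. A zero-variance
#' difference vector is degenerate: the p-value is then reported as the
#' machine-epsilon bound (or exactly 1 when all differences are zero) with
#' `degenerate = TRUE`.
#'
#' @param methodAccuracy,baselineAccuracy aligned per-feature accuracies.
#' @param methodBce,baselineBce mean binary cross-entropies.
#' @param method method label.
#' @param paired paired t test (default) or Welch.
#' @return a [ReconstructionReport-class].
#' @export
compareToBaseline <- function(methodAccuracy, baselineAccuracy,
                              methodBce = NA_real_, baselineBce = NA_real_,
                              method = "method", paired = TRUE) {
  stopifnot(length(methodAccuracy) == length(baselineAccuracy))
  if (length(methodAccuracy) < 3L)
    stop("need at least 3 features for the t test", call. = FALSE)
  diffs <- methodAccuracy - baselineAccuracy
  degenerate <- FALSE
  if (paired && stats::sd(diffs) == 0) {
    degenerate <- TRUE
    tStat <- if (all(diffs == 0)) 0 else sign(mean(diffs)) * Inf
    pVal <- if (all(diffs == 0)) 1 else .Machine$double.eps
  } else {
    tt <- if (paired) {
      stats::t.test(methodAccuracy, baselineAccuracy, paired = TRUE)
    } else {
      stats::t.test(methodAccuracy, baselineAccuracy, var.equal = FALSE)
    }
    tStat <- unname(tt$statistic)
    pVal <- tt$p.value
  }
  methods::new("ReconstructionReport",
    method = method,
    perFeatureAccuracy = methodAccuracy,
    baselinePerFeatureAccuracy = baselineAccuracy,
    meanAccuracy = mean(methodAccuracy),
    baselineMeanAccuracy = mean(baselineAccuracy),
    meanBce = methodBce,
    baselineMeanBce = baselineBce,
    tStatistic = tStat,
    tTestP = pVal,
    degenerate = degenerate)
}

#' Evaluate a feature selection by feature-space reconstruction
#'
#' Trains the reconstruction network on the training split, scores it and
#' the mode baseline on the test split (per-feature accuracy at the 0.5
#' threshold and mean binary cross-entropy), and compares accuracies with a
#' two-sided t test across features.
#'
#' @param train,test matched [RecordMatrix-class] splits (or matrices).
#' @param selection a [SelectionResult-class] or integer index vector.
#' @param seed integer seed for the reconstructor.
#' @param ... forwarded to [trainReconstructor()].
#' @return a [ReconstructionReport-class].
#' @export
evaluateReconstruction <- function(train, test, selection, seed = 1L, ...) {
  selected <- if (methods::is(selection, "SelectionResult")) {
    selection@selected
  } else {
    as.integer(selection)
  }
  label <- if (methods::is(selection, "SelectionResult")) {
    selection@method
  } else {
    "subset"
  }
  Xtr <- .sampleMatrix(train)
  Xte <- .sampleMatrix(test)
  model <- trainReconstructor(Xtr, selected, seed = seed, ...)
  P <- predictReconstruction(model, Xte)
  acc <- colMeans((P >= 0.5) == (Xte == 1))
  bce <- .bce(Xte, P)
  base <- modeBaseline(Xtr)
  baseAcc <- colMeans(sweep(Xte, 2L, base$mode, `==`))
  baseP <- matrix(.clipProb(base$prob), nrow(Xte), ncol(Xte), byrow = TRUE)
  baseBce <- .bce(Xte, baseP)
  compareToBaseline(acc, baseAcc, bce, baseBce, method = label)
}

setMethod("show", "ReconstructionReport", function(object) {
  cat("ReconstructionReport [", object@method, "]\n",
      "  mean accuracy: ", format(object@meanAccuracy, digits = 4),
      "  (baseline ", format(object@baselineMeanAccuracy, digits = 4), ")\n",
      "  mean BCE:      ", format(object@meanBce, digits = 4),
      "  (baseline ", format(object@baselineMeanBce, digits = 4), ")\n",
      "  t = ", format(object@tStatistic, digits = 4),
      ", p = ", format(object@tTestP, digits = 3),
      if (object@degenerate) "  [degenerate variance]" else "", "\n",
      sep = "")
})
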