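# Supervised validation track: rare-outcome prediction from the selected
# codes with gradient-boosted trees, plus the comparison statistics.

#' Upsample the minority class to balance a training set
#'
#' Minority rows are resampled with replacement until the class counts are
#' equal; majority rows are untouched. Deterministic given `seed`.
#'
#' @param x a [RecordMatrix-class] with its outcome set, or a
#'   samples-by-features matrix (then `y` is required).
#' @param y binary outcome vector when `x` is a plain matrix.
#' @param seed integer seed.
#' @return a balanced `RecordMatrix`, or `list(x, y)` for matrix input.
#' @export
upsampleMinority <- function(x, y = NULL, seed = 1L) {
  isRM <- methods::is(x, "RecordMatrix")
  yy <- if (isRM) outcome(x) else as.integer(y)
  if (anyNA(yy)) stop("outcome contains NA", call. = FALSE)
  tab <- table(factor(yy, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(tab)[which.min(tab)])
  nExtra <- abs(diff(as.integer(tab)))
  minIdx <- which(yy == minority)
  extra <- withSeed(seed, sample(minIdx, nExtra, replace = TRUE))
  idx <- c(seq_along(yy), extra)
  if (isRM) return(x[, idx])
  list(x = x[idx, , drop = FALSE], y = yy[idx])
}

.xgbFit <- function(X, y, hp, seed) {
  xgboost::xgb.train(
    params = xgboost::xgb.params(objective = "binary:logistic",
                                 max_depth = hp$max_depth, eta = hp$eta,
                                 min_child_weight = hp$min_child_weight,
                                 nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = hp$nrounds, verbose = 0)
}

.defaultXgbGrid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L), eta = c(0.05, 0.1, 0.3),
              nrounds = c(100L, 300L), min_child_weight = c(1, 5))
}

.stratifiedFolds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("too few samples in a class to build ", k, " stratified folds",
         call. = FALSE)
  withSeed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit a gradient-boosted-tree outcome model with cross-validated tuning
#'
#' Trains XGBoost classifiers over a small documented hyperparameter grid
#' (tree depth 3/5/7, learning rate 0.05/0.1/0.3, 100/300 trees, minimum
#' child weight 1/5 by default), picks the combination maximizing mean AUC
#' over seeded stratified `cvFolds`-fold cross-validation, and refits it on
#' the full training set. When `upsample` is on (the default), the minority
#' class is upsampled *within* each training fold and in the final fit,
#' while validation folds keep their original class balance: balancing
#' before the fold split would copy minority rows into the validation
#' folds and bias tuning toward overfit settings. Deterministic given
#' `seed` (single thread).
#'
#' @param x training [RecordMatrix-class] or matrix.
#' @param y binary outcome when `x` is a matrix.
#' @param selected non-empty feature column indices used as predictors.
#' @param cvFolds number of folds (default 5, at least 2).
#' @param seed integer seed.
#' @param grid data frame of hyperparameter combinations; default
#'   `.defaultXgbGrid()`-style grid.
#' @param upsample balance each training fold by minority upsampling
#'   (default `TRUE`); set to `FALSE` if `x` is already balanced.
#' @return a model handle for [predictOutcome()] and [shapleyImportance()].
#' @export
fitOutcomeModel <- function(x, y = NULL, selected, cvFolds = 5L, seed = 1L,
                            grid = NULL, upsample = TRUE) {
  isRM <- methods::is(x, "RecordMatrix")
  yy <- if (isRM) outcome(x) else as.integer(y)
  X <- .sampleMatrix(x)
  selected <- as.integer(selected)
  if (!length(selected)) stop("selected must be non-empty", call. = FALSE)
  stopifnot(cvFolds >= 2L)
  if (is.null(grid)) grid <- .defaultXgbGrid()
  codes <- .featureCodesOf(x, ncol(X))[selected]
  Xs <- X[, selected, drop = FALSE]
  colnames(Xs) <- codes
  fold <- .stratifiedFolds(yy, cvFolds, seed)
  foldTrain <- lapply(seq_len(cvFolds), function(f) {
    tr <- which(fold != f)
    if (length(unique(yy[fold == f])) < 2L)
      stop("degenerate validation fold", call. = FALSE)
    if (upsample) {
      up <- upsampleMinority(Xs[tr, , drop = FALSE], yy[tr],
                             seed = seed + f)
      up
    } else {
      list(x = Xs[tr, , drop = FALSE], y = yy[tr])
    }
  })
  cvAuc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(cvFolds)
    for (f in seq_len(cvFolds)) {
      bst <- .xgbFit(foldTrain[[f]]$x, foldTrain[[f]]$y, grid[g, ], seed)
      va <- which(fold == f)
      pr <- predict(bst, xgboost::xgb.DMatrix(Xs[va, , drop = FALSE]))
      aucs[f] <- .aucMW(pr, yy[va])
    }
    cvAuc[g] <- mean(aucs)
  }
  best <- which.max(cvAuc)
  final <- if (upsample) upsampleMinority(Xs, yy, seed = seed)
           else list(x = Xs, y = yy)
  booster <- .xgbFit(final$x, final$y, grid[best, ], seed)
  structure(list(booster = booster, selected = selected,
                 featureCodes = codes, nFeatures = ncol(X),
                 bestParams = grid[best, , drop = FALSE],
                 cvAuc = cvAuc[best]),
            class = "codesieve_outcome_model")
}

#' Predicted outcome probabilities
#'
#' @param model handle from [fitOutcomeModel()].
#' @param x a [RecordMatrix-class] or matrix on the same feature space.
#' @return numeric vector of probabilities.
#' @export
predictOutcome <- function(model, x) {
  X <- .sampleMatrix(x)
  if (ncol(X) != model$nFeatures)
    stop("feature mismatch between model and matrix", call. = FALSE)
  Xs <- X[, model$selected, drop = FALSE]
  colnames(Xs) <- model$featureCodes
  predict(model$booster, xgboost::xgb.DMatrix(Xs, nthread = 1L))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of two ROC curves computed from paired score
#' vectors on the same labeled rows, via placement values and their
#' covariance; two-sided normal p-value. The AUCs equal the Mann-Whitney
#' U-statistic AUCs.
#'
#' @param scoresA,scoresB score vectors on the same test rows.
#' @param labels binary labels; both classes must be present.
#' @return list with `aucA`, `aucB` and two-sided `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (stats::var(scoresA) == 0 || stats::var(scoresB) == 0)
    stop("constant score vector: ROC undefined", call. = FALSE)
  aucA <- .aucMW(scoresA, labels)
  aucB <- .aucMW(scoresB, labels)
  if (identical(as.numeric(scoresA), as.numeric(scoresB)))
    return(list(aucA = aucA, aucB = aucB, p = 1))
  rocA <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
  rocB <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
  tst <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  p <- tst$p.value
  if (!is.finite(p)) p <- 1
  list(aucA = aucA, aucB = aucB, p = p)
}

#' McNemar test on paired binary predictions
#'
#' Builds the discordant counts `b` (A right, B wrong) and `c` (A wrong, B
#' right); exact two-sided binomial test when `b + c < 25`, otherwise the
#' chi-square statistic with continuity correction
#' \eqn{(|b-c|-1)^2/(b+c)}. When `b + c = 0` the classifiers are
#' indistinguishable and `p = 1` is returned with a degeneracy flag.
#'
#' @param predA,predB binary predictions aligned with `labels`.
#' @param labels binary ground truth.
#' @return list with `p`, counts `b` and `c`, and `degenerate`.
#' @export
mcnemarTest <- function(predA, predB, labels) {
  stopifnot(length(predA) == length(labels),
            length(predB) == length(labels))
  rightA <- predA == labels
  rightB <- predB == labels
  b <- sum(rightA & !rightB)
  cc <- sum(!rightA & rightB)
  if (b + cc == 0)
    return(list(p = 1, b = b, c = cc, degenerate = TRUE))
  p <- if (b + cc < 25) {
    stats::binom.test(b, b + cc, 0.5)$p.value
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  list(p = min(p, 1), b = b, c = cc, degenerate = FALSE)
}

#' Per-row tree Shapley attributions
#'
#' Exact tree-path Shapley values from the gradient-boosted model; per row,
#' the attributions plus the bias term sum to the model's margin output.
#'
#' @param model handle from [fitOutcomeModel()].
#' @param x a [RecordMatrix-class] or matrix on the same feature space.
#' @return matrix rows x (features + BIAS column).
#' @export
shapleyValues <- function(model, x) {
  X <- .sampleMatrix(x)
  if (ncol(X) != model$nFeatures)
    stop("feature mismatch between model and matrix", call. = FALSE)
  Xs <- X[, model$selected, drop = FALSE]
  colnames(Xs) <- model$featureCodes
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(Xs, nthread = 1L),
                     predcontrib = TRUE)
  colnames(contrib) <- c(model$featureCodes, "BIAS")
  contrib
}

#' Mean absolute Shapley importance per selected feature
#'
#' @param model handle from [fitOutcomeModel()].
#' @param x test [RecordMatrix-class] or matrix.
#' @return named non-negative numeric vector, one entry per selected
#'   feature.
#' @export
shapleyImportance <- function(model, x) {
  contrib <- shapleyValues(model, x)
  v <- colMeans(abs(contrib[, colnames(contrib) != "BIAS", drop = FALSE]))
  names(v) <- model$featureCodes
  v
}

.welchP <- function(a, b) {
  if (length(a) == length(b) &&
      all(sort(a) == sort(b))) return(1)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1
           else .Machine$double.eps)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Compare selected-code depths and Shapley importances across methods
#'
#' Per method: the mean depth of its selected codes and a two-sided Welch t
#' test of its depth distribution against a reference method (default the
#' weight-adjusted CAE, which is built to select shallower codes). When
#' per-feature mean absolute Shapley vectors are supplied, the same
#' machinery compares importances. Methods with fewer than 3 selected
#' features are excluded with a warning.
#'
#' @param selections named list of [SelectionResult-class] objects.
#' @param hierarchy the [CodeHierarchy-class] the codes live in.
#' @param shap optional named list of mean-absolute-Shapley vectors.
#' @param reference name of the reference method (default `"caeww"`).
#' @return data frame with one row per method.
#' @export
depthImportanceComparison <- function(selections, hierarchy, shap = NULL,
                                      reference = "caeww") {
  stopifnot(length(selections) >= 2L, reference %in% names(selections))
  keep <- vapply(selections, function(s) length(s@selected) >= 3L,
                 logical(1))
  if (!all(keep)) {
    warning("excluding methods with fewer than 3 selected features: ",
            paste(names(selections)[!keep], collapse = ", "),
            call. = FALSE)
    selections <- selections[keep]
  }
  depths <- lapply(selections, function(s) {
    as.numeric(codeDepth(hierarchy, selectedFeatures(s)))
  })
  refDepth <- depths[[reference]]
  out <- data.frame(
    method = names(selections),
    n_selected = vapply(selections, function(s) length(s@selected),
                        integer(1)),
    mean_depth = vapply(depths, mean, numeric(1)),
    depth_p_vs_reference = vapply(depths, function(d) {
      .welchP(d, refDepth)
    }, numeric(1)),
    row.names = NULL
  )
  if (!is.null(shap)) {
    shap <- shap[names(selections)]
    refShap <- as.numeric(shap[[reference]])
    out$mean_abs_shapley <- vapply(shap, function(s) mean(as.numeric(s)),
                                   numeric(1))
    out$shapley_p_vs_reference <- vapply(shap, function(s) {
      .welchP(as.numeric(s), refShap)
    }, numeric(1))
  }
  out
}

#' Run the full outcome-prediction case study for one method
#'
#' Upsamples the minority class of the training split, fits the tuned
#' gradient-boosted model on the selected features, scores the held-out
#' test split (accuracy, F1 and AUC-ROC at the 0.5 probability threshold),
#' compares against a reference selection with the DeLong (AUC) and McNemar
#' (classification) tests, and reports per-feature mean absolute Shapley
#' values plus the mean depth of the selected codes.
#'
#' @param train,test [RecordMatrix-class] splits with outcomes set.
#' @param selection [SelectionResult-class] under evaluation.
#' @param referenceSelection optional reference [SelectionResult-class];
#'   when `NULL` the DeLong/McNemar p-values are `NA`.
#' @param seed integer seed.
#' @param cvFolds,grid forwarded to [fitOutcomeModel()].
#' @return a [CaseStudyReport-class].
#' @export
caseStudy <- function(train, test, selection, referenceSelection = NULL,
                      seed = 1L, cvFolds = 5L, grid = NULL) {
  yTest <- outcome(test)
  model <- fitOutcomeModel(train, selected = selection@selected,
                           cvFolds = cvFolds, seed = seed, grid = grid)
  prob <- predictOutcome(model, test)
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & yTest == 1)
  fp <- sum(pred == 1 & yTest == 0)
  fn <- sum(pred == 0 & yTest == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  delongP <- NA_real_
  mcnemarP <- NA_real_
  if (!is.null(referenceSelection)) {
    refModel <- fitOutcomeModel(train,
                                selected = referenceSelection@selected,
                                cvFolds = cvFolds, seed = seed, grid = grid)
    refProb <- predictOutcome(refModel, test)
    delongP <- delongTest(prob, refProb, yTest)$p
    mcnemarP <- mcnemarTest(pred, as.integer(refProb >= 0.5), yTest)$p
  }
  h <- codeHierarchy(train)
  methods::new("CaseStudyReport",
    method = selection@method,
    reference = if (is.null(referenceSelection)) NA_character_
                else referenceSelection@method,
    accuracy = mean(pred == yTest),
    f1 = f1,
    aucRoc = .aucMW(prob, yTest),
    delongP = delongP,
    mcnemarP = mcnemarP,
    shapMeanAbs = shapleyImportance(model, test),
    meanSelectedDepth = mean(codeDepth(h, selectedFeatures(selection))))
}

setMethod("show", "CaseStudyReport", function(object) {
  cat("CaseStudyReport [", object@method, "] vs reference [",
      object@reference, "]\n",
      "  accuracy ", format(object@accuracy, digits = 3),
      "  F1 ", format(object@f1, digits = 3),
      "  AUC-ROC ", format(object@aucRoc, digits = 3), "\n",
      "  DeLong p ", format(object@delongP, digits = 3),
      "  McNemar p ", format(object@mcnemarP, digits = 3), "\n",
      "  mean selected depth ",
      format(object@meanSelectedDepth, digits = 3), "\n", sep = "")
})
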