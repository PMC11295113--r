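#' @import methods
#' @importFrom stats rnorm runif rbinom rpois predict t.test pchisq binom.test
#'   kmeans sd var quantile plogis qlogis
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Rooted forest of hierarchical medical codes
#'
#' Holds an ICD-10-like or ATC-like code tree (or forest): every code has an
#' optional parent, a depth (roots sit at depth 0) and a free-text label.
#' Depth is what drives the loss weight \eqn{w = 1/(1+d)} used by the
#' weight-adjusted concrete autoencoder.
#'
#' @slot code character vector of unique code identifiers.
#' @slot parent character vector of parent codes; `NA` marks a root.
#' @slot depth integer vector, 0 for roots, parent depth + 1 otherwise.
#' @slot label character vector of human-readable labels.
#' @slot system character vector, one of `"ICD10"`, `"ATC"`, `"SYNTH"`.
#'
#' @export
setClass("CodeHierarchy",
  representation(
    code = "character",
    parent = "character",
    depth = "integer",
    label = "character",
    system = "character"
  )
)

setValidity("CodeHierarchy", function(object) {
  msgs <- character()
  n <- length(object@code)
  if (anyDuplicated(object@code))
    msgs <- c(msgs, "duplicated codes in hierarchy")
  if (length(object@parent) != n || length(object@depth) != n ||
      length(object@label) != n || length(object@system) != n)
    msgs <- c(msgs, "slot lengths differ")
  has_parent <- !is.na(object@parent)
  miss <- setdiff(object@parent[has_parent], object@code)
  if (length(miss))
    msgs <- c(msgs, paste0("missing parent codes: ",
                           paste(miss, collapse = ", ")))
  if (n && !length(msgs)) {
    pidx <- match(object@parent, object@code)
    root_ok <- object@depth[!has_parent] == 0L
    chain_ok <- object@depth[has_parent] ==
      object@depth[pidx[has_parent]] + 1L
    if (!all(root_ok)) msgs <- c(msgs, "root depth must be 0")
    if (!all(chain_ok)) msgs <- c(msgs, "depth must be parent depth + 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary record-by-code matrix with ancestor closure
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"onehot"` is a sparse binary matrix with code features as rows and
#' aggregated patient-period records as columns. Row metadata carries each
#' code's depth and parent; column metadata carries `patient_id`,
#' `window_index` and an optional binary `outcome`. The encoding guarantees
#' ancestor closure: whenever a code is present in a record, every ancestor
#' of that code is present too.
#'
#' @export
setClass("RecordMatrix", contains = "SummarizedExperiment")

setValidity("RecordMatrix", function(object) {
  msgs <- character()
  if (!"onehot" %in% SummarizedExperiment::assayNames(object))
    return("assay 'onehot' is required")
  a <- SummarizedExperiment::assay(object, "onehot")
  vals <- if (methods::is(a, "sparseMatrix")) a@x else as.numeric(a)
  if (length(vals) && !all(vals %in% c(0, 1)))
    msgs <- c(msgs, "onehot assay must be binary")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("patient_id", "window_index") %in% colnames(cd)))
    msgs <- c(msgs, "colData must have patient_id and window_index")
  if (length(msgs)) msgs else TRUE
})

#' Result of one feature-selection run
#'
#' @slot method short method name (`"ls"`, `"mcfs"`, `"aefs"`, `"pfa"`,
#'   `"cae"`, `"caeww"`).
#' @slot scores per-feature numeric scores oriented so that larger means more
#'   selected; `numeric(0)` for the concrete autoencoder, which ranks nothing.
#' @slot selected ordered unique feature indices, at most `nBest` of them.
#' @slot selectorAssignment for concrete autoencoders, the argmax feature of
#'   each selector neuron (length exactly `nBest`, duplicates allowed);
#'   `integer(0)` otherwise.
#' @slot featureCodes codes aligned with the feature index space.
#' @slot nBest the requested number of features.
#' @slot details method-specific extras (configuration echo, loss history).
#'
#' @export
setClass("SelectionResult",
  representation(
    method = "character",
    scores = "numeric",
    selected = "integer",
    selectorAssignment = "integer",
    featureCodes = "character",
    nBest = "integer",
    details = "list"
  )
)

setValidity("SelectionResult", function(object) {
  msgs <- character()
  p <- length(object@featureCodes)
  sel <- object@selected
  if (anyDuplicated(sel)) msgs <- c(msgs, "selected indices must be unique")
  if (length(sel) && (min(sel) < 1L || max(sel) > p))
    msgs <- c(msgs, "selected indices out of range")
  if (length(sel) > object@nBest)
    msgs <- c(msgs, "more than nBest features selected")
  if (length(object@selectorAssignment) &&
      !setequal(unique(object@selectorAssignment), sel))
    msgs <- c(msgs, "selected must equal unique(selectorAssignment)")
  if (length(msgs)) msgs else TRUE
})

#' Feature-space reconstruction report
#'
#' Per-feature accuracy and binary cross-entropy of a reconstruction network
#' driven by a selected feature subset, next to an input-independent mode
#' baseline, with a two-sided t test across features on the accuracy
#' difference.
#'
#' @export
setClass("ReconstructionReport",
  representation(
    method = "character",
    perFeatureAccuracy = "numeric",
    baselinePerFeatureAccuracy = "numeric",
    meanAccuracy = "numeric",
    baselineMeanAccuracy = "numeric",
    meanBce = "numeric",
    baselineMeanBce = "numeric",
    tStatistic = "numeric",
    tTestP = "numeric",
    degenerate = "logical"
  )
)

#' Outcome-prediction case-study report
#'
#' Metrics of a gradient-boosted-tree model predicting a rare binary outcome
#' from a selected feature set, with DeLong and McNemar comparisons against a
#' reference method, per-feature mean absolute Shapley values, and the mean
#' depth of the selected codes.
#'
#' @export
setClass("CaseStudyReport",
  representation(
    method = "character",
    reference = "character",
    accuracy = "numeric",
    f1 = "numeric",
    aucRoc = "numeric",
    delongP = "numeric",
    mcnemarP = "numeric",
    shapMeanAbs = "numeric",
    meanSelectedDepth = "numeric"
  )
)
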