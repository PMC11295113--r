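#' @rdname onehot
#' @export
setGeneric("onehot", function(x, ...) standardGeneric("onehot"))

#' @rdname featureCodes
#' @export
setGeneric("featureCodes", function(x) standardGeneric("featureCodes"))

#' @rdname recordMeta
#' @export
setGeneric("recordMeta", function(x) standardGeneric("recordMeta"))

#' @rdname outcome
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname outcome
#' @export
setGeneric("outcome<-", function(x, value) standardGeneric("outcome<-"))

#' @rdname codeHierarchy
#' @export
setGeneric("codeHierarchy", function(x) standardGeneric("codeHierarchy"))

#' @rdname selectedFeatures
#' @export
setGeneric("selectedFeatures", function(x, ...) {
  standardGeneric("selectedFeatures")
})

#' @rdname featureScores
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname laplacianScore
#' @export
setGeneric("laplacianScore", function(x, ...) standardGeneric("laplacianScore"))

#' @rdname mcfsScores
#' @export
setGeneric("mcfsScores", function(x, ...) standardGeneric("mcfsScores"))

#' @rdname aefsSelect
#' @export
setGeneric("aefsSelect", function(x, ...) standardGeneric("aefsSelect"))

#' @rdname pfaSelect
#' @export
setGeneric("pfaSelect", function(x, ...) standardGeneric("pfaSelect"))

#' @rdname caeSelect
#' @export
setGeneric("caeSelect", function(x, ...) standardGeneric("caeSelect"))
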