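.selectionResult <- function(method, scores, selected, featureCodes, nBest,
                             selectorAssignment = integer(0),
                             details = list()) {
  methods::new("SelectionResult",
    method = method,
    scores = if (is.null(scores)) numeric(0) else as.numeric(scores),
    selected = as.integer(selected),
    selectorAssignment = as.integer(selectorAssignment),
    featureCodes = featureCodes,
    nBest = as.integer(nBest),
    details = details
  )
}

# Top-n indices by score, largest first, ties broken by lowest index.
.topN <- function(scores, n) {
  order(-scores, seq_along(scores))[seq_len(min(n, length(scores)))]
}

#' @describeIn SelectionResult codes of the selected features.
#' @param x a `SelectionResult`.
#' @param ... unused.
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x, ...) {
  x@featureCodes[x@selected]
})

#' @describeIn SelectionResult per-feature scores (larger = more selected);
#'   `numeric(0)` for concrete autoencoders.
#' @export
setMethod("featureScores", "SelectionResult", function(x) {
  s <- x@scores
  if (length(s)) names(s) <- x@featureCodes
  s
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@method, "]: ",
      length(object@selected), " of ", length(object@featureCodes),
      " features (nBest = ", object@nBest, ")\n", sep = "")
  sel <- selectedFeatures(object)
  cat("  ", paste(utils::head(sel, 8L), collapse = ", "),
      if (length(sel) > 8L) ", ..." else "", "\n", sep = "")
})

#' Serialize a selection result to JSON
#'
#' @param result a [SelectionResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSelection <- function(result, path) {
  jsonlite::write_json(list(
    method = result@method,
    n_best = result@nBest,
    scores = if (length(result@scores)) result@scores else NULL,
    selected = result@selected,
    selected_codes = selectedFeatures(result),
    selector_assignment =
      if (length(result@selectorAssignment)) result@selectorAssignment
      else NULL,
    config = result@details$config
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
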