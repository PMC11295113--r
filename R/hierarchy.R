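# Code-tree plumbing: ATC codes are fixed-width so parents come from prefix
# truncation; ICD block codes (e.g. "I20-I25") cannot be inferred from child
# strings, so the ICD tree is table-driven.

.ATC_LEVEL_WIDTHS <- c(1L, 3L, 4L, 5L, 7L)

#' Ancestors of an ATC code by prefix truncation
#'
#' The ATC classification has five fixed-width levels (1, 3, 4, 5 and 7
#' characters). The proper ancestors of a code are its prefixes at the level
#' boundaries below its own, nearest first, e.g. `"C07AB02"` yields
#' `"C07AB"`, `"C07A"`, `"C07"`, `"C"`.
#'
#' @param code a single ATC code string.
#' @return character vector of proper ancestors, nearest first; empty for an
#'   anatomical main group (one-letter root).
#' @examples
#' parseAtcAncestors("C07AB02")
#' @export
parseAtcAncestors <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, !is.na(code))
  w <- nchar(code)
  patterns <- c(
    "1" = "^[A-Z]$",
    "3" = "^[A-Z][0-9]{2}$",
    "4" = "^[A-Z][0-9]{2}[A-Z]$",
    "5" = "^[A-Z][0-9]{2}[A-Z]{2}$",
    "7" = "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  )
  if (!w %in% .ATC_LEVEL_WIDTHS || !grepl(patterns[[as.character(w)]], code))
    stop("malformed ATC code: '", code, "'", call. = FALSE)
  widths <- rev(.ATC_LEVEL_WIDTHS[.ATC_LEVEL_WIDTHS < w])
  vapply(widths, function(k) substr(code, 1L, k), character(1))
}

.makeHierarchy <- function(code, parent, label, system) {
  methods::new("CodeHierarchy",
    code = as.character(code),
    parent = as.character(parent),
    depth = .computeDepths(code, parent),
    label = as.character(label),
    system = as.character(system)
  )
}

# depth by iterative resolution; detects orphans and cycles
.computeDepths <- function(code, parent) {
  n <- length(code)
  parent <- as.character(parent)
  miss <- setdiff(parent[!is.na(parent)], code)
  if (length(miss))
    stop("parent codes missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  depth <- rep(NA_integer_, n)
  depth[is.na(parent)] <- 0L
  pidx <- match(parent, code)
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(todo)) break
    depth[todo] <- depth[pidx[todo]] + 1L
  }
  if (anyNA(depth)) {
    bad <- which(is.na(depth))[1L]
    path <- code[bad]
    cur <- bad
    repeat {
      cur <- pidx[cur]
      path <- c(path, code[cur])
      if (code[cur] == code[bad]) break
      if (length(path) > n + 1L) break
    }
    stop("cycle in hierarchy: ", paste(path, collapse = " -> "),
         call. = FALSE)
  }
  depth
}

#' Build an ICD-style hierarchy from an explicit parent table
#'
#' ICD-10 chapters, blocks (like `"I20-I25"`), categories and expansion codes
#' form a tree that cannot be derived from code strings alone, so it is given
#' as a table with one row per code. An empty or `NA` parent marks a root
#' (chapter).
#'
#' @param codeTable data frame with columns `code`, `parent` and optionally
#'   `label`; rows unique by code.
#' @param system label for the coding system (default `"ICD10"`).
#' @return a [CodeHierarchy-class].
#' @export
buildIcdHierarchy <- function(codeTable, system = "ICD10") {
  stopifnot(is.data.frame(codeTable),
            all(c("code", "parent") %in% colnames(codeTable)))
  if (anyDuplicated(codeTable$code))
    stop("duplicated codes in hierarchy table", call. = FALSE)
  parent <- as.character(codeTable$parent)
  parent[!is.na(parent) & !nzchar(parent)] <- NA_character_
  label <- if ("label" %in% colnames(codeTable)) {
    as.character(codeTable$label)
  } else {
    rep("", nrow(codeTable))
  }
  .makeHierarchy(codeTable$code, parent, label,
                 rep(system, nrow(codeTable)))
}

#' Build an ATC hierarchy from the codes observed in the data
#'
#' Expands every observed code with all its prefix ancestors and wires the
#' parent links at the fixed ATC level boundaries.
#'
#' @param codes character vector of ATC codes at any level.
#' @return a [CodeHierarchy-class].
#' @export
buildAtcHierarchy <- function(codes) {
  codes <- unique(as.character(codes))
  all_codes <- unique(unlist(c(codes, lapply(codes, parseAtcAncestors))))
  all_codes <- sort(all_codes)
  parent <- vapply(all_codes, function(cd) {
    anc <- parseAtcAncestors(cd)
    if (length(anc)) anc[[1L]] else NA_character_
  }, character(1))
  .makeHierarchy(all_codes, unname(parent), rep("", length(all_codes)),
                 rep("ATC", length(all_codes)))
}

#' Read a hierarchy table from delimited text
#'
#' @param path CSV file with columns `code,parent,label`; empty parent = root.
#' @param system coding-system label.
#' @return a [CodeHierarchy-class].
#' @export
readHierarchy <- function(path, system = "ICD10") {
  tab <- utils::read.csv(path, colClasses = "character")
  buildIcdHierarchy(tab, system = system)
}

#' Ancestors of a code within a hierarchy
#'
#' @param hierarchy a [CodeHierarchy-class].
#' @param code a single code present in the hierarchy.
#' @return character vector of proper ancestors, nearest first.
#' @export
codeAncestors <- function(hierarchy, code) {
  i <- match(code, hierarchy@code)
  if (is.na(i)) stop("unknown code: '", code, "'", call. = FALSE)
  out <- character(0)
  repeat {
    p <- hierarchy@parent[i]
    if (is.na(p)) break
    out <- c(out, p)
    i <- match(p, hierarchy@code)
  }
  out
}

#' Depth of codes in a hierarchy (roots at 0)
#'
#' @param hierarchy a [CodeHierarchy-class].
#' @param codes character vector of codes.
#' @return integer vector of depths.
#' @export
codeDepth <- function(hierarchy, codes) {
  i <- match(codes, hierarchy@code)
  if (anyNA(i))
    stop("unknown codes: ", paste(codes[is.na(i)], collapse = ", "),
         call. = FALSE)
  hierarchy@depth[i]
}

#' Depth-based loss weight
#'
#' The weight \eqn{w(d) = 1/(1+d)} given to a feature at tree depth `d` in
#' the weight-adjusted concrete autoencoder's reconstruction loss: general
#' codes near the roots (depth 0, weight 1) matter most, and the weight
#' decreases strictly with depth.
#'
#' @param depth non-negative integer depth(s).
#' @return numeric weights in (0, 1].
#' @examples
#' depthWeight(0:3) # 1, 1/2, 1/3, 1/4
#' @export
depthWeight <- function(depth) {
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be non-negative", call. = FALSE)
  1 / (1 + depth)
}

#' @describeIn CodeHierarchy number of codes.
#' @param x a `CodeHierarchy`.
#' @export
setMethod("length", "CodeHierarchy", function(x) length(x@code))

setMethod("show", "CodeHierarchy", function(object) {
  cat("CodeHierarchy with", length(object@code), "codes (",
      sum(is.na(object@parent)), "roots ), systems:",
      paste(unique(object@system), collapse = "/"),
      "\n  max depth:", if (length(object@depth)) max(object@depth) else 0,
      "\n")
})

# Extend a hierarchy with codes not present in its table: each becomes a
# depth-0 singleton root (Canadian ICD-10-CA extensions make complete tables
# unrealistic, so unknown codes are kept, not dropped).
.augmentHierarchy <- function(hierarchy, codes) {
  unknown <- setdiff(codes, hierarchy@code)
  if (!length(unknown)) return(hierarchy)
  warning("attaching ", length(unknown),
          " unknown code(s) as depth-0 roots: ",
          paste(utils::head(unknown, 5L), collapse = ", "),
          if (length(unknown) > 5L) ", ..." else "", call. = FALSE)
  methods::new("CodeHierarchy",
    code = c(hierarchy@code, unknown),
    parent = c(hierarchy@parent, rep(NA_character_, length(unknown))),
    depth = c(hierarchy@depth, rep(0L, length(unknown))),
    label = c(hierarchy@label, rep("", length(unknown))),
    system = c(hierarchy@system, rep("SYNTH", length(unknown)))
  )
}
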