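# Long-format records -> aggregated windows -> ancestor-closed one-hot matrix.

#' Read long-format clinical code records
#'
#' @param path CSV file with columns `patient_id,date,code,system` and
#'   ISO-8601 dates.
#' @return data frame with a parsed `date` column.
#' @export
readRecords <- function(path) {
  rec <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("patient_id", "date", "code") %in% colnames(rec)))
  d <- as.Date(rec$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1L]
    stop("unparseable date at row ", bad, ": '", rec$date[bad], "'",
         call. = FALSE)
  }
  rec$date <- d
  rec
}

#' Aggregate code records into fixed-length windows per patient
#'
#' For every patient, windows are consecutive half-open intervals of
#' `windowDays` days anchored at that patient's first event date. Each
#' non-empty window becomes one aggregated record whose code set is the union
#' of the codes observed in the window; empty windows yield no record. Three
#' months of hospital codes is emulated as 90 days, six months of pharmacy
#' codes as 180 days.
#'
#' @param records data frame with columns `patient_id`, `date` (a `Date` or
#'   ISO-8601 string) and `code`.
#' @param windowDays positive window length in days.
#' @return data frame with columns `patient_id`, `window_index` (0-based) and
#'   a list column `codes` of unique code sets.
#' @export
aggregateRecords <- function(records, windowDays) {
  stopifnot(is.data.frame(records), windowDays > 0)
  dates <- records$date
  if (!inherits(dates, "Date")) {
    parsed <- as.Date(as.character(dates), format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1L]
      stop("unparseable date at row ", bad, ": '", dates[bad], "'",
           call. = FALSE)
    }
    dates <- parsed
  }
  pid <- as.character(records$patient_id)
  first <- tapply(as.integer(dates), pid, min)
  win <- (as.integer(dates) - as.integer(first[pid])) %/% as.integer(windowDays)
  key <- paste(pid, win, sep = "\r")
  groups <- split(as.character(records$code), key)
  ord <- order(names(groups))
  groups <- groups[ord]
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(parts, `[[`, character(1), 1L),
    window_index = as.integer(vapply(parts, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
  out$codes <- lapply(groups, function(g) sort(unique(g)))
  ord2 <- order(out$patient_id, out$window_index)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-hot encode aggregated records with ancestor closure
#'
#' Columns are the union of all observed codes and all their ancestors in the
#' hierarchy, sorted by code. A record carrying a code also carries every
#' ancestor of that code (ancestor closure), mirroring how a specific
#' diagnosis implies its category, block and chapter. Codes absent from the
#' hierarchy are attached as depth-0 singleton roots with a warning.
#'
#' @param aggregated output of [aggregateRecords()].
#' @param hierarchy a [CodeHierarchy-class].
#' @return a [RecordMatrix-class].
#' @export
encodeOneHot <- function(aggregated, hierarchy) {
  stopifnot(is.data.frame(aggregated), "codes" %in% colnames(aggregated))
  observed <- unique(unlist(aggregated$codes))
  hierarchy <- .augmentHierarchy(hierarchy, observed)
  anc <- lapply(observed, function(cd) codeAncestors(hierarchy, cd))
  names(anc) <- observed
  features <- sort(unique(c(observed, unlist(anc))))
  fidx <- seq_along(features)
  names(fidx) <- features
  closures <- lapply(observed, function(cd) {
    unname(fidx[c(cd, anc[[cd]])])
  })
  names(closures) <- observed
  rows_i <- integer(0)
  rows_j <- integer(0)
  for (r in seq_len(nrow(aggregated))) {
    j <- sort(unique(unlist(closures[aggregated$codes[[r]]])))
    rows_i <- c(rows_i, rep.int(r, length(j)))
    rows_j <- c(rows_j, j)
  }
  m <- Matrix::sparseMatrix(i = rows_i, j = rows_j, x = 1,
                            dims = c(nrow(aggregated), length(features)),
                            dimnames = list(NULL, features))
  .newRecordMatrix(m, aggregated$patient_id, aggregated$window_index,
                   hierarchy)
}

.newRecordMatrix <- function(onehot, patient_id, window_index, hierarchy,
                             outcome = NULL) {
  features <- colnames(onehot)
  depth <- codeDepth(hierarchy, features)
  pidx <- match(features, hierarchy@code)
  cd <- S4Vectors::DataFrame(
    patient_id = as.character(patient_id),
    window_index = as.integer(window_index)
  )
  cd$outcome <- if (is.null(outcome)) NA_integer_ else as.integer(outcome)
  rd <- S4Vectors::DataFrame(
    code = features,
    depth = depth,
    parent = hierarchy@parent[pidx]
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(onehot = Matrix::t(onehot)),
    rowData = rd, colData = cd,
    metadata = list(hierarchy = hierarchy)
  )
  methods::new("RecordMatrix", se)
}

#' @describeIn RecordMatrix the binary matrix as records x features
#'   (transpose of the stored assay).
#' @param x a `RecordMatrix`.
#' @param dense return a base dense matrix instead of a sparse one.
#' @param ... unused.
#' @export
setMethod("onehot", "RecordMatrix", function(x, dense = FALSE, ...) {
  m <- Matrix::t(SummarizedExperiment::assay(x, "onehot"))
  if (dense) as.matrix(m) else m
})

#' @describeIn RecordMatrix codes aligned with the feature rows.
#' @export
setMethod("featureCodes", "RecordMatrix", function(x) {
  as.character(SummarizedExperiment::rowData(x)$code)
})

#' @describeIn RecordMatrix per-record metadata (patients, windows, outcome).
#' @export
setMethod("recordMeta", "RecordMatrix", function(x) {
  SummarizedExperiment::colData(x)
})

#' @describeIn RecordMatrix binary outcome per record (`NA` when unset).
#' @export
setMethod("outcome", "RecordMatrix", function(x) {
  SummarizedExperiment::colData(x)$outcome
})

#' @describeIn RecordMatrix attach a binary outcome vector.
#' @param value integer/logical vector, one value per record.
#' @export
setMethod("outcome<-", "RecordMatrix", function(x, value) {
  stopifnot(length(value) == ncol(x))
  SummarizedExperiment::colData(x)$outcome <- as.integer(value)
  methods::validObject(x)
  x
})

#' @describeIn RecordMatrix the hierarchy the matrix was encoded against.
#' @export
setMethod("codeHierarchy", "RecordMatrix", function(x) {
  S4Vectors::metadata(x)$hierarchy
})

setMethod("show", "RecordMatrix", function(object) {
  cat("RecordMatrix:", ncol(object), "records x", nrow(object),
      "code features\n  patients:",
      length(unique(SummarizedExperiment::colData(object)$patient_id)),
      "  outcome set:",
      !all(is.na(SummarizedExperiment::colData(object)$outcome)), "\n")
})

#' Check ancestor closure of an encoded matrix
#'
#' @param x a [RecordMatrix-class].
#' @return `TRUE` if every record that carries a code also carries all of the
#'   code's ancestors present in the feature set.
#' @export
validateClosure <- function(x) {
  m <- onehot(x)
  features <- featureCodes(x)
  h <- codeHierarchy(x)
  parent <- h@parent[match(features, h@code)]
  pidx <- match(parent, features)
  for (j in seq_along(features)) {
    if (is.na(pidx[j])) next
    if (any(m[, j] > m[, pidx[j]])) return(FALSE)
  }
  TRUE
}

#' Split records into train and test partitions at the patient level
#'
#' All of a patient's records land in exactly one partition, mirroring the
#' patient-level 67/33 split used when selected features must generalize to
#' unseen patients. The mechanism is a seeded shuffle of patient identifiers.
#'
#' @param x a [RecordMatrix-class] with at least two distinct patients.
#' @param trainFraction fraction of patients assigned to training, in (0,1).
#' @param seed integer seed; same seed, same partition.
#' @return list with elements `train` and `test`, both `RecordMatrix`.
#' @export
splitByPatient <- function(x, trainFraction = 0.67, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  pid <- as.character(SummarizedExperiment::colData(x)$patient_id)
  patients <- unique(pid)
  if (length(patients) < 2L)
    stop("need at least 2 distinct patients to split", call. = FALSE)
  shuffled <- withSeed(seed, sample(patients))
  nTrain <- round(trainFraction * length(patients))
  nTrain <- max(1L, min(length(patients) - 1L, nTrain))
  trainSet <- shuffled[seq_len(nTrain)]
  list(train = x[, pid %in% trainSet], test = x[, !pid %in% trainSet])
}

#' Write a record matrix as plain-text files
#'
#' Emits `matrix.mtx` (MatrixMarket, records x features), `features.csv`
#' (code, depth, parent) and `records.csv` (patient, window, outcome).
#'
#' @param x a [RecordMatrix-class].
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
writeRecordMatrix <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(onehot(x), file.path(dir, "matrix.mtx"))
  utils::write.csv(as.data.frame(SummarizedExperiment::rowData(x)),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(SummarizedExperiment::colData(x)),
                   file.path(dir, "records.csv"), row.names = FALSE)
  invisible(dir)
}
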