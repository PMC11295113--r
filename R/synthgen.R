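# Synthetic hierarchical code data with transparent ground truth: latent
# comorbidity factors emit characteristic leaf codes across dated records,
# ancestor closure is added downstream by the encoder, and a rare binary
# outcome is driven by a sparse subset of codes.

#' Synthetic-data configuration
#'
#' Defaults emulate the record structure the analysis assumes: a few hundred
#' patients with a handful of dated records each, a balanced code tree,
#' disjoint latent comorbidity factors emitting correlated leaf-code blocks,
#' a small random flip noise, and a rare outcome (5% positive) driven by
#' five codes with log-odds weight 1.5 each.
#'
#' @param nPatients number of patients.
#' @param recordsPerPatient mean of the per-patient record-count
#'   distribution (Poisson, shifted to be at least 1).
#' @param hierarchyShape `c(nRoots, branching, nLevels)` of the balanced
#'   synthetic code tree.
#' @param nLatent number of latent comorbidity factors.
#' @param factorActivationProb probability a patient has a given factor.
#' @param emissionProb per-code emission probability of an active factor.
#' @param redundancyRate probability a factor's sibling codes co-fire
#'   deterministically (one draw shared within each sibling group).
#' @param outcomeCodes number of codes driving the outcome.
#' @param outcomeWeight log-odds contribution of each outcome code.
#' @param outcomePrevalence target positive rate, in (0, 0.5).
#' @param noiseFlip probability of a random independent leaf code per
#'   record.
#' @param spanDays calendar span of each patient's records in days.
#' @param seed integer seed.
#' @return a validated list of class `synth_config`.
#' @export
synthConfig <- function(nPatients = 500L, recordsPerPatient = 6,
                        hierarchyShape = c(4L, 3L, 3L), nLatent = 5L,
                        factorActivationProb = 0.3, emissionProb = 0.9,
                        redundancyRate = 0, outcomeCodes = 5L,
                        outcomeWeight = 1.5, outcomePrevalence = 0.05,
                        noiseFlip = 0.01, spanDays = 360L, seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients),
              recordsPerPatient = recordsPerPatient,
              hierarchyShape = as.integer(hierarchyShape),
              nLatent = as.integer(nLatent),
              factorActivationProb = factorActivationProb,
              emissionProb = emissionProb,
              redundancyRate = redundancyRate,
              outcomeCodes = as.integer(outcomeCodes),
              outcomeWeight = outcomeWeight,
              outcomePrevalence = outcomePrevalence,
              noiseFlip = noiseFlip, spanDays = as.integer(spanDays),
              seed = as.integer(seed))
  probs <- c(cfg$factorActivationProb, cfg$emissionProb,
             cfg$redundancyRate, cfg$noiseFlip)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$outcomePrevalence > 0, cfg$outcomePrevalence < 0.5,
            cfg$nPatients >= 2L, length(cfg$hierarchyShape) == 3L,
            cfg$hierarchyShape[3L] >= 2L)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a balanced synthetic code hierarchy
#'
#' Codes are path-encoded strings (`"R1"`, `"R1.2"`, `"R1.2.3"`, ...) so a
#' node's depth is verifiable from its string alone. The construction is
#' deterministic.
#'
#' @param nRoots number of roots (depth-0 codes).
#' @param branching children per node.
#' @param nLevels number of levels including the roots (at least 2).
#' @param seed accepted for interface symmetry; the tree is deterministic.
#' @return a [CodeHierarchy-class] with system `"SYNTH"`.
#' @export
generateHierarchy <- function(nRoots, branching, nLevels, seed = 1L) {
  stopifnot(nLevels >= 2L, nRoots >= 1L, branching >= 1L)
  code <- paste0("R", seq_len(nRoots))
  parent <- rep(NA_character_, nRoots)
  level <- code
  for (l in seq_len(nLevels - 1L)) {
    child <- as.vector(t(outer(level, seq_len(branching), paste, sep = ".")))
    parent <- c(parent, rep(level, each = branching))
    code <- c(code, child)
    level <- child
  }
  .makeHierarchy(code, parent, rep("", length(code)),
                 rep("SYNTH", length(code)))
}

.leafCodes <- function(hierarchy) {
  setdiff(hierarchy@code, hierarchy@parent[!is.na(hierarchy@parent)])
}

#' Generate a synthetic long-format record stream with ground truth
#'
#' Each patient draws latent factor activations; active factors emit their
#' characteristic leaf codes (per-code emission probability
#' `emissionProb`) across dated records spanning multiple aggregation
#' windows. Factors flagged redundant share one emission draw per sibling
#' group, so those siblings co-fire deterministically. Independent random
#' leaf codes are added with probability `noiseFlip`. Byte-identical given
#' the configuration seed.
#'
#' @param config a [synthConfig()] list.
#' @param hierarchy a [CodeHierarchy-class]; default generated from
#'   `config$hierarchyShape`.
#' @return list with `records` (patient_id, date, code, system) and `truth`
#'   (generator code sets, redundant sibling groups, outcome codes and
#'   weights, the hierarchy).
#' @export
generateRecords <- function(config, hierarchy = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(hierarchy)) {
    hierarchy <- generateHierarchy(config$hierarchyShape[1L],
                                   config$hierarchyShape[2L],
                                   config$hierarchyShape[3L])
  }
  leaves <- sort(.leafCodes(hierarchy))
  stopifnot(length(leaves) >= config$nLatent)
  withSeed(config$seed, {
    shuffled <- sample(leaves)
    factorSets <- split(shuffled,
                        rep_len(seq_len(config$nLatent), length(shuffled)))
    factorSets <- lapply(factorSets, sort)
    names(factorSets) <- paste0("factor", seq_len(config$nLatent))
    redundant <- stats::runif(config$nLatent) < config$redundancyRate
    siblingGroups <- lapply(factorSets, function(set) {
      par <- hierarchy@parent[match(set, hierarchy@code)]
      grp <- split(set, par)
      grp[vapply(grp, length, integer(1)) >= 2L]
    })
    nOut <- min(config$outcomeCodes, config$nLatent)
    outCodes <- vapply(factorSets[seq_len(nOut)], `[[`, character(1), 1L)
    if (config$outcomeCodes > nOut) {
      pool <- setdiff(leaves, outCodes)
      outCodes <- c(outCodes,
                    sample(pool, config$outcomeCodes - nOut))
    }
    outCodes <- unname(outCodes)
    pids <- sprintf("P%04d", seq_len(config$nPatients))
    origin <- as.Date("2020-01-01")
    acc <- vector("list", config$nPatients)
    for (i in seq_len(config$nPatients)) {
      active <- which(stats::rbinom(config$nLatent, 1L,
                                    config$factorActivationProb) == 1L)
      nRec <- stats::rpois(1L, max(config$recordsPerPatient - 1, 0)) + 1L
      dates <- origin + sort(sample.int(config$spanDays, nRec,
                                        replace = TRUE)) - 1L
      recs <- vector("list", nRec)
      for (r in seq_len(nRec)) {
        codes <- character(0)
        for (f in active) {
          set <- factorSets[[f]]
          if (redundant[f] && length(siblingGroups[[f]])) {
            grouped <- unlist(siblingGroups[[f]], use.names = FALSE)
            solo <- setdiff(set, grouped)
            fire <- stats::runif(length(siblingGroups[[f]])) <
              config$emissionProb
            codes <- c(codes,
                       unlist(siblingGroups[[f]][fire], use.names = FALSE),
                       solo[stats::runif(length(solo)) <
                              config$emissionProb])
          } else {
            codes <- c(codes,
                       set[stats::runif(length(set)) < config$emissionProb])
          }
        }
        noise <- leaves[stats::runif(length(leaves)) < config$noiseFlip]
        codes <- unique(c(codes, noise))
        if (length(codes)) {
          recs[[r]] <- data.frame(patient_id = pids[i],
                                  date = dates[r], code = codes,
                                  system = "SYNTH",
                                  stringsAsFactors = FALSE)
        }
      }
      acc[[i]] <- do.call(rbind, recs)
    }
    records <- do.call(rbind, acc)
    rownames(records) <- NULL
    truth <- list(generatorCodes = factorSets,
                  redundantFactors = which(redundant),
                  siblingGroups = siblingGroups,
                  outcomeCodes = outCodes,
                  outcomeWeights = rep(config$outcomeWeight,
                                       length(outCodes)),
                  hierarchy = hierarchy)
    list(records = records, truth = truth)
  })
}

#' Attach a rare binary outcome driven by planted codes
#'
#' The per-record log-odds are an intercept plus the sum of the planted
#' codes' weights over the codes present in the record. The intercept is
#' calibrated by bisection so the expected prevalence matches
#' `config$outcomePrevalence`; labels are then drawn with the given seed.
#'
#' @param x an encoded [RecordMatrix-class] containing the outcome codes.
#' @param truth the `truth` component of [generateRecords()].
#' @param config the [synthConfig()] used.
#' @param seed integer seed for the label draw.
#' @return the `RecordMatrix` with its outcome set; the realized prevalence
#'   is in `metadata(x)$outcome_prevalence`.
#' @export
generateOutcome <- function(x, truth, config, seed = config$seed) {
  codes <- truth$outcomeCodes
  miss <- setdiff(codes, featureCodes(x))
  if (length(miss))
    stop("outcome codes absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- onehot(x)
  s <- as.numeric(X[, codes, drop = FALSE] %*% truth$outcomeWeights)
  target <- config$outcomePrevalence
  lo <- -40
  hi <- 40
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (mean(stats::plogis(mid + s)) > target) hi <- mid else lo <- mid
  }
  a <- (lo + hi) / 2
  p <- stats::plogis(a + s)
  if (abs(mean(p) - target) / target > 0.2)
    stop("outcome calibration failed; achieved expected prevalence ",
         signif(mean(p), 3), call. = FALSE)
  y <- withSeed(seed, stats::rbinom(length(p), 1L, p))
  outcome(x) <- y
  S4Vectors::metadata(x)$outcome_prevalence <- mean(y)
  S4Vectors::metadata(x)$outcome_intercept <- a
  x
}

#' Planted duplicated-generator matrix for selector recovery experiments
#'
#' A small number of independent binary generator columns is expanded into
#' many noisy duplicates: two columns are equivalent when they were
#' identical before the flip noise. A selector asked for one feature per
#' generator should recover (near) full group coverage.
#'
#' @param nSamples rows.
#' @param nGenerators independent generator columns (default 8).
#' @param nDuplicates copies per generator (default 8).
#' @param flipNoise per-entry flip probability (default 0.05).
#' @param generatorProb Bernoulli rate of the generators (default 0.5).
#' @param seed integer seed.
#' @return list with the binary matrix `x` (samples x
#'   `nGenerators * nDuplicates`) and `groups`, the generator index of every
#'   column.
#' @export
makeDuplicatedMatrix <- function(nSamples, nGenerators = 8L,
                                 nDuplicates = 8L, flipNoise = 0.05,
                                 generatorProb = 0.5, seed = 1L) {
  withSeed(seed, {
    B <- matrix(stats::rbinom(nSamples * nGenerators, 1L, generatorProb),
                nSamples, nGenerators)
    groups <- rep(seq_len(nGenerators), each = nDuplicates)
    X <- B[, groups, drop = FALSE]
    flips <- matrix(stats::rbinom(length(X), 1L, flipNoise), nrow(X))
    X <- abs(X - flips)
    colnames(X) <- paste0("G", groups, ".", sequence(rep(nDuplicates,
                                                         nGenerators)))
    list(x = X, groups = groups)
  })
}

#' Parent-child redundancy data for the depth-weighting experiment
#'
#' Builds a forest of `nUnits` roots with two leaf children each; children
#' fire independently with probability `childProb` per record and the
#' encoder's ancestor closure makes every root the OR of its children, so a
#' child deterministically implies its parent. At `childProb` near 0.55 the
#' unweighted reconstruction trade-off between picking a root or a child is
#' close to neutral, which is exactly where the depth weighting should tip
#' selection toward the ancestors.
#'
#' @param nUnits number of root-children units (default 8).
#' @param nSamples number of records.
#' @param childProb per-child firing probability (default 0.55).
#' @param seed integer seed.
#' @return an encoded [RecordMatrix-class] (`3 * nUnits` features).
#' @export
makeParentChildData <- function(nUnits = 8L, nSamples = 300L,
                                childProb = 0.55, seed = 1L) {
  h <- generateHierarchy(nUnits, 2L, 2L)
  children <- sort(.leafCodes(h))
  withSeed(seed, {
    codes <- lapply(seq_len(nSamples), function(i) {
      children[stats::runif(length(children)) < childProb]
    })
    agg <- data.frame(patient_id = sprintf("P%04d", seq_len(nSamples)),
                      window_index = 0L, stringsAsFactors = FALSE)
    agg$codes <- codes
    suppressWarnings(encodeOneHot(agg, h))
  })
}

#' Write synthetic records, hierarchy and truth to plain-text files
#'
#' @param sim output of [generateRecords()].
#' @param recordsPath,hierarchyPath,truthPath output files (CSV, CSV, JSON).
#' @return invisibly, the three paths.
#' @export
writeSynthData <- function(sim, recordsPath, hierarchyPath, truthPath) {
  rec <- sim$records
  rec$date <- format(rec$date, "%Y-%m-%d")
  utils::write.csv(rec, recordsPath, row.names = FALSE)
  h <- sim$truth$hierarchy
  utils::write.csv(data.frame(code = h@code,
                              parent = ifelse(is.na(h@parent), "",
                                              h@parent),
                              label = h@label),
                   hierarchyPath, row.names = FALSE)
  jsonlite::write_json(list(
    generator_codes = sim$truth$generatorCodes,
    outcome_codes = sim$truth$outcomeCodes,
    outcome_weights = sim$truth$outcomeWeights
  ), truthPath, auto_unbox = FALSE, digits = NA)
  invisible(c(recordsPath, hierarchyPath, truthPath))
}
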