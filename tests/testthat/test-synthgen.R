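test_that("balanced hierarchies have the expected shape and depths", {
  h <- generateHierarchy(2, 3, 3)
  expect_equal(length(h), 2 + 6 + 18)
  # depth is recoverable from the path-encoded code string
  for (cd in h@code) {
    expect_equal(codeDepth(h, cd), lengths(regmatches(cd,
                  gregexpr(".", cd, fixed = TRUE))))
  }
  expect_identical(generateHierarchy(2, 3, 3), generateHierarchy(2, 3, 3))
})

test_that("a single always-active factor emits only its own codes", {
  cfg <- synthConfig(nPatients = 30, nLatent = 1,
                     factorActivationProb = 1, noiseFlip = 0, seed = 4)
  sim <- generateRecords(cfg)
  expect_true(all(sim$records$code %in% sim$truth$generatorCodes[[1]]))
})

test_that("the record stream is byte-identical under one seed", {
  cfg <- synthConfig(nPatients = 40, seed = 77)
  a <- generateRecords(cfg)
  b <- generateRecords(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$outcomeCodes, b$truth$outcomeCodes)
})

test_that("codes correlate more within a factor than between factors", {
  cfg <- synthConfig(nPatients = 300, nLatent = 4,
                     factorActivationProb = 0.4, noiseFlip = 0.01,
                     seed = 15)
  sim <- generateRecords(cfg)
  agg <- aggregateRecords(sim$records, 90)
  rmx <- encodeOneHot(agg, sim$truth$hierarchy)
  X <- as.matrix(onehot(rmx))
  sets <- sim$truth$generatorCodes
  pick <- function(s) X[, intersect(s, colnames(X))[1:3]]
  within <- mean(cor(pick(sets[[1]]))[upper.tri(diag(3))])
  between <- mean(cor(pick(sets[[1]]), pick(sets[[2]])))
  expect_gt(within, between)
})

test_that("redundant sibling groups co-fire exactly when noise is off", {
  cfg <- synthConfig(nPatients = 60, nLatent = 2, redundancyRate = 1,
                     factorActivationProb = 0.5, noiseFlip = 0, seed = 8)
  sim <- generateRecords(cfg)
  agg <- aggregateRecords(sim$records, 90)
  rmx <- encodeOneHot(agg, sim$truth$hierarchy)
  X <- as.matrix(onehot(rmx))
  expect_true(length(sim$truth$redundantFactors) >= 1)
  for (f in sim$truth$redundantFactors) {
    for (grp in sim$truth$siblingGroups[[f]]) {
      cols <- intersect(grp, colnames(X))
      if (length(cols) < 2) next
      for (j in cols[-1]) expect_identical(X[, cols[1]], X[, j])
    }
  }
})

test_that("encoded synthetic matrices always satisfy ancestor closure", {
  for (sd in c(3, 9)) {
    cfg <- synthConfig(nPatients = 50, seed = sd, noiseFlip = 0.05)
    sim <- generateRecords(cfg)
    rmx <- encodeOneHot(aggregateRecords(sim$records, 90),
                        sim$truth$hierarchy)
    expect_true(validateClosure(rmx))
  }
})

test_that("outcome prevalence is calibrated across seeds", {
  prevs <- vapply(1:10, function(sd) {
    cfg <- synthConfig(nPatients = 1600, outcomePrevalence = 0.05,
                       nLatent = 8, seed = sd)
    sim <- generateRecords(cfg)
    rmx <- encodeOneHot(aggregateRecords(sim$records, 90),
                        sim$truth$hierarchy)
    rmx <- generateOutcome(rmx, sim$truth, cfg, seed = sd)
    mean(outcome(rmx))
  }, numeric(1))
  expect_true(all(abs(prevs - 0.05) / 0.05 <= 0.2))
})

test_that("zero weights reduce the outcome to pure calibrated noise", {
  cfg <- synthConfig(nPatients = 400, outcomeWeight = 0,
                     outcomePrevalence = 0.1, seed = 21)
  sim <- generateRecords(cfg)
  rmx <- encodeOneHot(aggregateRecords(sim$records, 90),
                      sim$truth$hierarchy)
  rmx <- generateOutcome(rmx, sim$truth, cfg, seed = 21)
  # with all weights zero every record has identical probability = target
  expect_equal(S4Vectors::metadata(rmx)$outcome_intercept,
               stats::qlogis(0.1), tolerance = 1e-6)
  expect_lt(abs(mean(outcome(rmx)) - 0.1) / 0.1, 0.2)
})

test_that("an overwhelming weight makes the outcome track its code", {
  cfg <- synthConfig(nPatients = 400, outcomeCodes = 1,
                     outcomeWeight = 60, outcomePrevalence = 0.32,
                     nLatent = 4, factorActivationProb = 0.3, seed = 33)
  sim <- generateRecords(cfg)
  rmx <- encodeOneHot(aggregateRecords(sim$records, 90),
                      sim$truth$hierarchy)
  rmx <- generateOutcome(rmx, sim$truth, cfg, seed = 33)
  x <- as.numeric(onehot(rmx)[, sim$truth$outcomeCodes])
  expect_gt(mean(outcome(rmx) == x), 0.9)
})

test_that("synthetic data writes to plain-text files", {
  cfg <- synthConfig(nPatients = 15, seed = 2)
  sim <- generateRecords(cfg)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("records.csv", "hier.csv", "truth.json"))
  writeSynthData(sim, paths[1], paths[2], paths[3])
  expect_true(all(file.exists(paths)))
  reread <- readRecords(paths[1])
  expect_equal(nrow(reread), nrow(sim$records))
  h2 <- readHierarchy(paths[2], system = "SYNTH")
  expect_setequal(h2@code, sim$truth$hierarchy@code)
})
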