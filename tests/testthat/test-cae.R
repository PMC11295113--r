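test_that("temperature schedule hits its endpoints and geometric midpoint", {
  expect_equal(caeTemperature(0), 20)
  expect_equal(caeTemperature(1000), 0.01)
  expect_equal(caeTemperature(500), sqrt(20 * 0.01), tolerance = 1e-12)
  expect_equal(caeTemperature(0, epochs = 200), 20)
  expect_equal(caeTemperature(200, epochs = 200), 0.01)
  expect_error(caeTemperature(-1), "0, epochs")
  expect_error(caeTemperature(1001), "0, epochs")
  expect_error(caeTemperature(5, tempStart = 0.01, tempEnd = 20))
})

test_that("selection stays within nBest, unique, argmax-consistent", {
  withr::with_seed(1, X <- matrix(rbinom(60 * 12, 1, 0.4), 60, 12))
  res <- caeSelect(X, nBest = 5, epochs = 30, batchSize = 16, seed = 4)
  expect_lte(length(res@selected), 5L)
  expect_false(anyDuplicated(res@selected) > 0)
  expect_length(res@selectorAssignment, 5L)
  expect_setequal(unique(res@selectorAssignment), res@selected)
  expect_length(res@scores, 0L)
  expect_error(caeSelect(X, nBest = 13), "exceeds")
})

test_that("selector neurons can collapse onto one dominant feature", {
  # only column 1 carries information (the rest are structurally absent
  # codes), so every neuron converges to it: the selection then holds
  # duplicates and strictly fewer distinct features than nBest
  withr::with_seed(2, base <- rbinom(200, 1, 0.5))
  X <- cbind(base, matrix(0, 200, 7))
  res <- caeSelect(X, nBest = 3, epochs = 120, batchSize = 16,
                   learningRate = 0.015, seed = 1)
  expect_lt(length(res@selected), 3L)
  expect_length(res@selectorAssignment, 3L)
})

test_that("training is bit-deterministic given the seed", {
  withr::with_seed(3, X <- matrix(rbinom(50 * 10, 1, 0.5), 50, 10))
  a <- caeSelect(X, nBest = 4, epochs = 25, seed = 7)
  b <- caeSelect(X, nBest = 4, epochs = 25, seed = 7)
  expect_identical(a@selectorAssignment, b@selectorAssignment)
  expect_identical(a@details$lossHistory, b@details$lossHistory)
  expect_identical(a@details$logits, b@details$logits)
})

test_that("all-ones feature weights reproduce the unweighted run exactly", {
  withr::with_seed(5, X <- matrix(rbinom(50 * 8, 1, 0.5), 50, 8))
  nw <- caeSelect(X, nBest = 3, epochs = 25, seed = 2)
  ww <- caeSelect(X, nBest = 3, epochs = 25, seed = 2,
                  featureWeights = rep(1, 8))
  expect_identical(nw@selectorAssignment, ww@selectorAssignment)
  expect_identical(nw@details$lossHistory, ww@details$lossHistory)
  expect_identical(nw@details$logits, ww@details$logits)
  expect_equal(ww@method, "caeww")
})

test_that("smoothed training loss decreases from start to finish", {
  d <- makeDuplicatedMatrix(200, 4, 4, 0.05, seed = 9)
  res <- caeSelect(d$x, nBest = 4, epochs = 100, batchSize = 16,
                   learningRate = 0.01, seed = 3)
  lh <- res@details$lossHistory
  expect_lt(mean(utils::tail(lh, 10)), mean(utils::head(lh, 10)))
})

test_that("feature weights outside (0,1] are rejected", {
  withr::with_seed(6, X <- matrix(rbinom(30 * 5, 1, 0.5), 30, 5))
  expect_error(caeSelect(X, nBest = 2, epochs = 5, featureWeights = rep(2, 5)),
               "featureWeights")
  expect_error(caeSelect(X, nBest = 2, epochs = 5, featureWeights = rep(1, 4)),
               "featureWeights")
})
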