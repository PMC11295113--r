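test_that("mode baseline is the analytic majority with ties to absence", {
  X <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))
  base <- modeBaseline(X)
  expect_equal(base$mode, c(1, 0, 0))  # column 3 is a 50/50 tie -> 0
  expect_equal(base$prob, c(1, 0.25, 0.5))
  Xte <- rbind(c(1, 0, 0), c(0, 0, 1))
  acc <- colMeans(sweep(Xte, 2, base$mode, `==`))
  expect_equal(acc, c(0.5, 1, 0.5))
})

test_that("baseline accuracy equals max(p, 1-p) when train and test agree", {
  withr::with_seed(4, {
    p <- c(0.1, 0.3, 0.8, 0.95)
    Xtr <- sapply(p, function(q) rbinom(300, 1, q))
    Xte <- sapply(p, function(q) rbinom(300, 1, q))
  })
  base <- modeBaseline(Xtr)
  acc <- colMeans(sweep(Xte, 2, base$mode, `==`))
  phat <- colMeans(Xte)
  expect_equal(acc, pmax(phat, 1 - phat))
})

test_that("accuracy comparison matches the closed-form paired t test", {
  withr::with_seed(2, {
    a <- runif(40, 0.8, 1)
    b <- runif(40, 0.8, 1)
  })
  rep <- compareToBaseline(a, b)
  expect_equal(rep@tTestP, pairedTOracle(a, b), tolerance = 1e-10)

  same <- compareToBaseline(a, a)
  expect_equal(same@tStatistic, 0)
  expect_equal(same@tTestP, 1)
  expect_true(same@degenerate)

  shifted <- compareToBaseline(a + 0.01, a)
  expect_true(shifted@degenerate)
  expect_lte(shifted@tTestP, .Machine$double.eps)

  expect_error(compareToBaseline(a[1:2], b[1:2]), "3 features")
})

test_that("reconstruction training helps and is seed-deterministic", {
  d <- makeDuplicatedMatrix(150, 4, 4, 0.05, seed = 21)
  m1 <- trainReconstructor(d$x, selected = c(1, 5, 9, 13), seed = 5,
                           epochs = 40)
  m2 <- trainReconstructor(d$x, selected = c(1, 5, 9, 13), seed = 5,
                           epochs = 40)
  expect_identical(m1$finalLoss, m2$finalLoss)
  expect_lt(m1$finalLoss, m1$initialLoss)
  expect_error(trainReconstructor(d$x, integer(0)), "non-empty")
})

test_that("informative selections beat the mode baseline, blind ones do not", {
  d <- makeDuplicatedMatrix(220, 4, 4, 0.05, seed = 31)
  train <- d$x[1:150, ]
  test <- d$x[151:220, ]
  full <- evaluateReconstruction(train, test, seq_len(ncol(train)),
                                 seed = 2, epochs = 60)
  expect_lt(full@meanBce, full@baselineMeanBce)
  expect_gt(full@meanAccuracy, full@baselineMeanAccuracy)

  blind <- cbind(const = 1, d$x)
  rep0 <- evaluateReconstruction(blind[1:150, ], blind[151:220, ],
                                 1L, seed = 2, epochs = 40)
  expect_lt(abs(rep0@meanAccuracy - rep0@baselineMeanAccuracy), 0.02)
})

test_that("the mode baseline is permutation-equivariant", {
  withr::with_seed(9, X <- matrix(rbinom(60 * 6, 1, 0.3), 60, 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  b1 <- modeBaseline(X)
  b2 <- modeBaseline(X[, perm])
  expect_equal(b2$mode, b1$mode[perm])
  expect_equal(b2$prob, b1$prob[perm])
})
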