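test_that("minority upsampling balances classes with exact copies", {
  withr::with_seed(3, X <- matrix(rbinom(100 * 5, 1, 0.3), 100, 5))
  y <- c(rep(0, 90), rep(1, 10))
  up <- upsampleMinority(X, y, seed = 2)
  expect_equal(as.integer(table(up$y)), c(90L, 90L))
  extras <- up$x[101:180, , drop = FALSE]
  pool <- X[91:100, , drop = FALSE]
  for (r in seq_len(nrow(extras))) {
    expect_true(any(apply(pool, 1, function(z) all(z == extras[r, ]))))
  }
  balanced <- upsampleMinority(X[1:20, ], rep(0:1, 10), seed = 1)
  expect_equal(nrow(balanced$x), 20L)
  expect_error(upsampleMinority(X, rep(0, 100)), "both classes")
})

test_that("a noiseless threshold outcome yields perfect held-out AUC", {
  withr::with_seed(5, X <- matrix(rbinom(200 * 6, 1, 0.4), 200, 6))
  y <- X[, 2]
  grid <- data.frame(max_depth = 2L, eta = 0.3, nrounds = 30L,
                     min_child_weight = 1)
  m <- fitOutcomeModel(X[1:150, ], y[1:150], selected = 1:6,
                       cvFolds = 3L, seed = 1, grid = grid)
  pr <- predictOutcome(m, X[151:200, ])
  expect_equal(CodeSieve:::.aucMW(pr, y[151:200]), 1)
})

test_that("permuted labels give chance-level AUC", {
  withr::with_seed(11, {
    X <- matrix(rbinom(2000 * 10, 1, 0.3), 2000, 10)
    y <- rbinom(2000, 1, 0.3)
  })
  grid <- data.frame(max_depth = 3L, eta = 0.3, nrounds = 30L,
                     min_child_weight = 1)
  m <- fitOutcomeModel(X[1:1400, ], y[1:1400], selected = 1:10,
                       cvFolds = 3L, seed = 2, grid = grid)
  auc <- CodeSieve:::.aucMW(predictOutcome(m, X[1401:2000, ]),
                            y[1401:2000])
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("DeLong comparison is symmetric with Mann-Whitney AUCs", {
  withr::with_seed(6, {
    y <- rbinom(200, 1, 0.3)
    a <- y + rnorm(200)
    b <- 0.5 * y + rnorm(200)
  })
  res <- delongTest(a, b, y)
  # independent AUC: integral of the empirical ROC via the rank formula
  expect_equal(res$aucA, rankAuc(a, y), tolerance = 1e-10)
  expect_equal(res$aucB, rankAuc(b, y), tolerance = 1e-10)
  swapped <- delongTest(b, a, y)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  expect_equal(swapped$aucA, res$aucB)

  same <- delongTest(a, a, y)
  expect_equal(same$p, 1)
  expect_error(delongTest(rep(1, 200), b, y), "constant")
})

test_that("McNemar matches its closed forms", {
  labels <- rep(1, 60)
  predA <- rep(1, 60)
  predB <- c(rep(0, 15), rep(1, 45))  # b = 15, c = 0
  res <- mcnemarTest(predA, predB, labels)
  expect_equal(res$b, 15L)
  expect_equal(res$c, 0L)
  expect_equal(res$p, 2 * 0.5^15, tolerance = 1e-12)

  same <- mcnemarTest(predB, predB, labels)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  labels2 <- rep(1, 80)
  predA2 <- c(rep(1, 60), rep(0, 20))           # 20 wrong
  predB2 <- c(rep(0, 40), rep(1, 40))           # first 40 wrong
  res2 <- mcnemarTest(predA2, predB2, labels2)  # b = 40, c = 20
  expect_equal(c(res2$b, res2$c), c(40L, 20L))
  expect_equal(res2$p,
               pchisq((abs(40 - 20) - 1)^2 / 60, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("tree Shapley attributions satisfy additivity", {
  withr::with_seed(8, {
    X <- matrix(rbinom(300 * 8, 1, 0.4), 300, 8)
    y <- as.integer(X[, 1] + X[, 4] + rnorm(300, sd = 0.5) > 1)
  })
  grid <- data.frame(max_depth = 3L, eta = 0.3, nrounds = 40L,
                     min_child_weight = 1)
  m <- fitOutcomeModel(X, y, selected = 1:8, cvFolds = 3L, seed = 3,
                       grid = grid, upsample = FALSE)
  contrib <- shapleyValues(m, X)
  margin <- predict(m$booster,
                    xgboost::xgb.DMatrix(
                      {
                        Xs <- X
                        colnames(Xs) <- m$featureCodes
                        Xs
                      }),
                    outputmargin = TRUE)
  expect_lt(max(abs(rowSums(contrib) - margin)), 1e-4)
  imp <- shapleyImportance(m, X)
  expect_length(imp, 8L)
  expect_true(all(imp >= 0))
  expect_true(all(order(-imp)[1:2] %in% c(1L, 4L)))
  expect_error(shapleyValues(m, X[, 1:5]), "mismatch")
})

test_that("depth and importance comparisons behave analytically", {
  h <- generateHierarchy(3, 2, 3)
  codes <- h@code
  mk <- function(method, sel) {
    CodeSieve:::.selectionResult(method, NULL, sel, codes, length(sel))
  }
  roots <- match(paste0("R", 1:3), codes)
  deep <- match(c("R1.1", "R1.1.2", "R2.1.1", "R3.2.2"), codes)
  tab <- depthImportanceComparison(
    list(caeww = mk("caeww", roots), ls = mk("ls", deep)), h)
  expect_equal(tab$mean_depth[tab$method == "caeww"], 0)
  expect_equal(tab$mean_depth[tab$method == "ls"], 1.75)
  expect_equal(tab$depth_p_vs_reference[tab$method == "caeww"], 1)
  expect_equal(tab$depth_p_vs_reference[tab$method == "ls"],
               welchOracle(c(1, 2, 2, 2), c(0, 0, 0)), tolerance = 1e-10)

  expect_equal(CodeSieve:::.welchP(c(0, 1, 2), c(2, 3, 4)),
               welchOracle(c(0, 1, 2), c(2, 3, 4)), tolerance = 1e-10)

  expect_warning(
    depthImportanceComparison(
      list(caeww = mk("caeww", roots), tiny = mk("tiny", roots[1:2])), h),
    "fewer than 3")
})
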