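smallBenchConfig <- function(seed, methods) {
  cfg <- demoBenchmarkConfig(seed = seed)
  cfg$methods <- methods
  cfg$synth$n_patients <- 80L
  cfg$cae$epochs <- 25L
  cfg$aefs$epochs <- 25L
  cfg$reconstruction$epochs <- 20L
  cfg
}

test_that("stage seeds derive deterministically and stay integer", {
  s1 <- CodeSieve:::.deriveSeed(1L, "synth")
  expect_identical(s1, CodeSieve:::.deriveSeed(1L, "synth"))
  expect_false(s1 == CodeSieve:::.deriveSeed(1L, "split"))
  expect_true(is.integer(CodeSieve:::.deriveSeed(2147483L, "case_study")))
})

test_that("a single-method run yields exactly one report row", {
  out <- runBenchmark(smallBenchConfig(3L, "ls"))
  expect_equal(nrow(out$report), 1L)
  expect_equal(out$report$method, "ls")
  expect_null(out$depth_comparison)
})

test_that("the report schema carries both evaluation tracks per method", {
  out <- runBenchmark(smallBenchConfig(5L, c("ls", "pfa", "caeww")))
  expect_setequal(out$report$method, c("ls", "pfa", "caeww"))
  expect_true(all(c("mean_accuracy", "baseline_mean_accuracy", "mean_bce",
                    "baseline_mean_bce", "accuracy_t_p",
                    "outcome_accuracy", "outcome_f1", "outcome_auc",
                    "delong_p_vs_reference", "mcnemar_p_vs_reference",
                    "mean_abs_shapley", "mean_selected_depth")
                  %in% colnames(out$report)))
  # reference method is compared to itself: NA p-values by construction
  ref <- out$report[out$report$method == "caeww", ]
  expect_true(is.na(ref$delong_p_vs_reference))
  expect_true(all(is.finite(
    out$report$delong_p_vs_reference[out$report$method != "caeww"])))
  expect_true(all(out$report$outcome_auc >= 0 &
                  out$report$outcome_auc <= 1))
})

test_that("benchmark artifacts are written when an output dir is given", {
  dir <- withr::local_tempdir()
  out <- runBenchmark(smallBenchConfig(2L, "pfa"), outDir = dir)
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "selection_pfa.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "matrix", "matrix.mtx")))
  expect_true(all(file.exists(file.path(dir, out$manifest$artifacts))))
})
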