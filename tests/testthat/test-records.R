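test_that("aggregation windows are per-patient half-open day intervals", {
  rec <- data.frame(
    patient_id = "a",
    date = as.Date("2020-01-01") + c(0, 45, 100),
    code = c("I251", "I25", "I200"))
  agg <- aggregateRecords(rec, 90)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$window_index, c(0L, 1L))
  expect_setequal(agg$codes[[1]], c("I25", "I251"))
  expect_equal(agg$codes[[2]], "I200")

  one <- aggregateRecords(data.frame(patient_id = "p",
                                     date = as.Date("2020-05-01"),
                                     code = "C07"), 180)
  expect_equal(nrow(one), 1L)
  expect_equal(one$codes[[1]], "C07")
})

test_that("interleaved patients anchor windows at their own first dates", {
  rec <- data.frame(
    patient_id = c("a", "b", "a", "b"),
    date = as.Date("2020-01-01") + c(0, 50, 80, 139),
    code = c("X1", "X2", "X3", "X4"))
  agg <- aggregateRecords(rec, 90)
  # both of b's events fall in b's first window (days 0 and 89 from day 50)
  expect_equal(agg$window_index[agg$patient_id == "b"], 0L)
  expect_setequal(agg$codes[[which(agg$patient_id == "b")]], c("X2", "X4"))
  expect_equal(agg$window_index[agg$patient_id == "a"], 0L)
})

test_that("unparseable dates are rejected with the row index", {
  rec <- data.frame(patient_id = "a", date = c("2020-01-01", "garbage"),
                    code = c("X", "Y"))
  expect_error(aggregateRecords(rec, 90), "row 2")
})

test_that("aggregation never loses or invents codes and never adds rows", {
  set.seed(11)
  rec <- data.frame(
    patient_id = sample(sprintf("p%d", 1:5), 60, replace = TRUE),
    date = as.Date("2020-01-01") + sample(0:400, 60, replace = TRUE),
    code = sample(c("A", "B", "C", "D"), 60, replace = TRUE))
  agg <- aggregateRecords(rec, 90)
  expect_lte(nrow(agg), nrow(rec))
  for (p in unique(rec$patient_id)) {
    expect_setequal(unique(unlist(agg$codes[agg$patient_id == p])),
                    unique(rec$code[rec$patient_id == p]))
  }
})

test_that("one-hot encoding adds all ancestors and keeps closure", {
  h <- buildIcdHierarchy(miniIcdTable())
  agg <- data.frame(patient_id = c("a", "b", "c"), window_index = 0L)
  agg$codes <- list("I251", "I25", "I200")
  rmx <- encodeOneHot(agg, h)
  m <- as.matrix(onehot(rmx))
  expect_equal(sort(featureCodes(rmx)),
               sort(c("I251", "I25", "I20-I25", "Chapter IX",
                      "I200", "I20")))
  expect_equal(unname(m[1, c("I251", "I25", "I20-I25", "Chapter IX")]),
               rep(1, 4))
  expect_equal(unname(m[2, "I251"]), 0)
  expect_equal(unname(m[2, "I25"]), 1)
  expect_true(validateClosure(rmx))

  root <- encodeOneHot({
    a <- data.frame(patient_id = "a", window_index = 0L)
    a$codes <- list("Chapter IX")
    a
  }, h)
  expect_equal(featureCodes(root), "Chapter IX")
})

test_that("codes missing from the hierarchy become depth-0 roots", {
  h <- buildIcdHierarchy(miniIcdTable())
  agg <- data.frame(patient_id = "a", window_index = 0L)
  agg$codes <- list(c("I251", "ZZZ9"))
  expect_warning(rmx <- encodeOneHot(agg, h), "ZZZ9")
  expect_equal(codeDepth(codeHierarchy(rmx), "ZZZ9"), 0L)
  expect_true(validateClosure(rmx))
})

test_that("patient-level split is exclusive, seeded and reproducible", {
  h <- generateHierarchy(2, 2, 2)
  agg <- data.frame(patient_id = rep(sprintf("p%d", 1:6), each = 2),
                    window_index = rep(0:1, 6))
  agg$codes <- rep(list("R1.1"), 12)
  rmx <- encodeOneHot(agg, h)
  sp <- splitByPatient(rmx, 0.67, seed = 5)
  trainP <- unique(recordMeta(sp$train)$patient_id)
  testP <- unique(recordMeta(sp$test)$patient_id)
  expect_length(intersect(trainP, testP), 0)
  expect_equal(ncol(sp$train) + ncol(sp$test), ncol(rmx))
  sp2 <- splitByPatient(rmx, 0.67, seed = 5)
  expect_identical(recordMeta(sp2$train)$patient_id,
                   recordMeta(sp$train)$patient_id)

  two <- rmx[, recordMeta(rmx)$patient_id %in% c("p1", "p2")]
  sp3 <- splitByPatient(two, 0.5, seed = 1)
  expect_length(unique(recordMeta(sp3$train)$patient_id), 1)
  expect_length(unique(recordMeta(sp3$test)$patient_id), 1)

  solo <- rmx[, recordMeta(rmx)$patient_id == "p1"]
  expect_error(splitByPatient(solo, 0.5, seed = 1), "2 distinct patients")
})

test_that("record matrices round-trip to plain-text files", {
  h <- buildIcdHierarchy(miniIcdTable())
  agg <- data.frame(patient_id = c("a", "b"), window_index = 0L)
  agg$codes <- list("I251", "I200")
  rmx <- encodeOneHot(agg, h)
  dir <- withr::local_tempdir()
  writeRecordMatrix(rmx, dir)
  expect_true(all(file.exists(file.path(dir, c("matrix.mtx",
                                               "features.csv",
                                               "records.csv")))))
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(unname(as.matrix(m) * 1), unname(as.matrix(onehot(rmx))))
})
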