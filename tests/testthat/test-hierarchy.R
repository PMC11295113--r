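test_that("ATC ancestors come from prefix truncation at level boundaries", {
  expect_equal(parseAtcAncestors("C07AB02"),
               c("C07AB", "C07A", "C07", "C"))
  expect_equal(parseAtcAncestors("C"), character(0))
  expect_equal(parseAtcAncestors("C07A"), c("C07", "C"))
  expect_error(parseAtcAncestors("C0"), "malformed")
  expect_error(parseAtcAncestors("C07AB0"), "malformed")
  expect_error(parseAtcAncestors("c07ab02"), "malformed")
})

test_that("ATC ancestor lists are suffix-consistent under re-parsing", {
  for (code in c("C07AB02", "N02BE01", "A10BA02")) {
    anc <- parseAtcAncestors(code)
    for (i in seq_along(anc)) {
      expect_equal(parseAtcAncestors(anc[i]),
                   anc[seq.int(i + 1, length.out = length(anc) - i)])
    }
  }
})

test_that("table-driven ICD hierarchy resolves chains, orphans and cycles", {
  h <- buildIcdHierarchy(miniIcdTable())
  expect_equal(codeAncestors(h, "I251"),
               c("I25", "I20-I25", "Chapter IX"))
  expect_equal(codeDepth(h, c("Chapter IX", "I20-I25", "I25", "I251")),
               0:3)
  single <- buildIcdHierarchy(data.frame(code = "X", parent = ""))
  expect_equal(codeDepth(single, "X"), 0L)
  expect_error(
    buildIcdHierarchy(data.frame(code = "A", parent = "B")),
    "missing.*B")
  expect_error(
    buildIcdHierarchy(data.frame(code = c("A", "B"), parent = c("B", "A"))),
    "cycle")
  expect_error(
    buildIcdHierarchy(data.frame(code = c("A", "A"), parent = c("", ""))),
    "duplicated")
})

test_that("depth equals ancestor-list length on every loaded hierarchy", {
  for (h in list(buildIcdHierarchy(miniIcdTable()),
                 buildAtcHierarchy(c("C07AB02", "C07AA05", "N02BE01")),
                 generateHierarchy(3, 2, 4))) {
    for (cd in h@code) {
      expect_equal(codeDepth(h, cd), length(codeAncestors(h, cd)))
    }
  }
})

test_that("depth weight is 1/(1+d), strictly decreasing, and validated", {
  expect_identical(depthWeight(0), 1)
  expect_identical(depthWeight(1), 0.5)
  expect_identical(depthWeight(3), 0.25)
  w <- depthWeight(0:10)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(depthWeight(-1), "non-negative")
})
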