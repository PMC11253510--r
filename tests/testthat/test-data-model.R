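test_that("delimited expression files parse with marker names and reserved columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD3,CD34", "1,4", "2,5", "3,6"), f)
  m <- readExpression(f)
  expect_s4_class(m, "CytoExpression")
  expect_equal(dim(exprValues(m)), c(3L, 2L))
  expect_identical(markerNames(m), c("CD3", "CD34"))
  expect_false(isTransformed(m))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD3,CD34,__label__,__sample__",
               "1,4,T,S1", "2,5,B,S1", "3,6,T,S2"), f2)
  m2 <- readExpression(f2)
  expect_identical(markerNames(m2), c("CD3", "CD34"))
  expect_identical(cellLabels(m2), c("T", "B", "T"))
  expect_identical(sampleIds(m2), c("S1", "S1", "S2"))
})

test_that("malformed delimited input fails loudly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD3,CD34", "1,4", "oops,5"), f)
  expect_error(readExpression(f), "non-numeric.*CD3.*row")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD3,CD3", "1,4"), f2)
  expect_error(readExpression(f2), "duplicate marker names.*CD3")

  expect_error(readExpression(file.path(tempdir(), "absent.csv")),
               "file not found")
})

test_that("FCS 3.0 files round-trip through the reader", {
  vals <- matrix(c(0.5, 1.25, 3, 10, 200.5, 0.031), nrow = 3,
                 dimnames = list(NULL, c("CD3", "CD34")))
  f <- withr::local_tempfile(fileext = ".fcs")
  writeTinyFCS(f, vals)
  m <- readExpression(f)
  expect_identical(markerNames(m), c("CD3", "CD34"))
  # float32 storage limits precision
  expect_equal(exprValues(m), vals, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("an FCS file with zero events is rejected", {
  f <- withr::local_tempfile(fileext = ".fcs")
  writeTinyFCS(f, matrix(numeric(0), 0, 2,
                         dimnames = list(NULL, c("a", "b"))))
  expect_error(readExpression(f), "0 events")
})

test_that("delimited write-then-read reproduces values and marker order", {
  withr::with_seed(42, {
    m <- cytoExpression(matrix(rnorm(60) * 100, 20, 3,
                               dimnames = list(NULL, c("zz", "aa", "mm"))),
                        cellLabels = sample(c("A", "B"), 20, TRUE),
                        sampleIds = sample(c("S1", "S2"), 20, TRUE))
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(m, f, format = "tsv")
  back <- readExpression(f)
  expect_identical(markerNames(back), markerNames(m))
  expect_equal(exprValues(back), exprValues(m), tolerance = 1e-9)
  expect_identical(cellLabels(back), cellLabels(m))
  expect_identical(sampleIds(back), sampleIds(m))
})

test_that("arcsinh transform matches the closed form and inverts exactly", {
  m <- cytoExpression(matrix(c(0, 5, -5, 50), 2, 2,
                             dimnames = list(NULL, c("a", "b"))))
  tr <- arcsinhTransform(m, cofactor = 5)
  expect_true(isTransformed(tr))
  expect_equal(unname(exprValues(tr)[1, 1]), 0)
  expect_equal(unname(exprValues(tr)[2, 1]), asinh(1))
  expect_equal(unname(exprValues(tr)[2, 1]), 0.881373587, tolerance = 1e-8)
  # strict monotonicity per entry and exact inversion
  withr::with_seed(1, x <- sort(rnorm(100, sd = 20)))
  mx <- cytoExpression(matrix(x, ncol = 1, dimnames = list(NULL, "m")))
  tx <- exprValues(arcsinhTransform(mx))
  expect_true(all(diff(tx) > 0))
  expect_equal(exprValues(inverseArcsinhTransform(arcsinhTransform(mx))),
               exprValues(mx), tolerance = 1e-9)
})

test_that("degenerate transform requests are errors", {
  m <- cytoExpression(matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(arcsinhTransform(m, cofactor = 0), "positive")
  tr <- arcsinhTransform(m)
  expect_error(arcsinhTransform(tr), "already")
  expect_s4_class(arcsinhTransform(tr, force = TRUE), "CytoExpression")
})

test_that("reference filtering applies the minimum-cell threshold", {
  means <- list(A = c(0, 0), B = c(4, 0), C = c(0, 4))
  ref <- makeReference(list(A = 500, B = 299, C = 300), means)
  out <- filterReference(ref, 300)
  expect_identical(sort(names(cellTypeCounts(out))), c("A", "C"))
  expect_identical(out@minCellsFilter, 300L)
  expect_identical(cellTypeCounts(filterReference(ref, 1)),
                   cellTypeCounts(ref))
  tiny <- makeReference(list(A = 10), list(A = c(0, 0)))
  expect_error(filterReference(tiny, 300), "below")
})

test_that("filtering never increases counts and retained types meet the threshold", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      counts <- as.list(sample(50:600, 6))
      names(counts) <- LETTERS[1:6]
      means <- lapply(1:6, function(i) rnorm(2, sd = 3))
      names(means) <- LETTERS[1:6]
      ref <- makeReference(counts, means, seed = rep)
      thr <- sample(100:500, 1)
      out <- tryCatch(filterReference(ref, thr), error = function(e) NULL)
      if (is.null(out)) {
        expect_true(all(unlist(counts) < thr))
      } else {
        after <- cellTypeCounts(out)
        expect_true(all(after >= thr))
        expect_true(all(after <= unlist(counts)[names(after)]))
      }
    }
  })
})

test_that("panel harmonization is exact intersection in reference order", {
  expect_identical(harmonizePanels(c("CD3", "CD34", "CD99"),
                                   c("CD3", "CD34", "CD8")),
                   c("CD3", "CD34"))
  # reference order wins
  expect_identical(harmonizePanels(c("CD34", "CD3"), c("CD3", "CD34")),
                   c("CD3", "CD34"))
  expect_error(harmonizePanels(c("a", "b"), c("c", "d")),
               "no shared backbone")
  # a 15-marker phenotyping panel shared in full
  bb <- c("CD11b", "CD8a", "CD33", "CD34", "CD3", "CD123", "CD56", "CD14",
          "CD117", "CD38", "CD4", "CD16", "CD20", "CD45", "CD7")
  expect_length(harmonizePanels(c(bb, "CD66b"), c(bb, "CD10")), 15L)
})

test_that("alias maps canonicalize names before matching", {
  cfg <- panelConfig(backbone = c("CD3", "CD34"),
                     aliasMap = c("CD3e" = "CD3", "CD34-bio" = "CD34"))
  expect_identical(harmonizePanels(c("CD3e", "CD34-bio", "CD99"),
                                   c("CD3", "CD34"), cfg),
                   c("CD3", "CD34"))
})

test_that("panel config rejects overlapping marker roles", {
  expect_error(panelConfig(backbone = c("CD3", "pErk"),
                           signaling = c("pErk", "pS6")),
               "disjoint")
  expect_error(panelConfig(arcsinhCofactor = -1), "positive")
})

test_that("survival tables derive and check the 60-month grouping", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,survival_months", "P1,59.9", "P2,60", "P3,3"), f)
  tab <- readSurvivalTable(f)
  expect_identical(tab$group, c("STS", "LTS", "STS"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,survival_months", "P1,LTS,10"), f2)
  expect_error(readSurvivalTable(f2), "inconsistent")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group", "P1,STS", "P1,LTS"), f3)
  expect_error(readSurvivalTable(f3), "duplicate")
})

test_that("validity catches label/shape mismatches", {
  m <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(cytoExpression(m, cellLabels = "onlyone"), "one entry per cell")
  expect_error(cytoExpression(matrix(1:4, 2, 2)), "column names")
  expect_silent(validObject(cytoExpression(m)))
})
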