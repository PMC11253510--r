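cohortLabels <- function(nSTS = 28, nLTS = 15)
  rep(c("STS", "LTS"), c(nSTS, nLTS))

test_that("hold-out splits are stratified, disjoint and exhaustive", {
  y <- cohortLabels()
  for (r in 1:10) {
    sp <- splitHoldout(y, testFrac = 0.2, valFrac = 0.4, seed = 3,
                       repeatIndex = r)
    expect_true(length(sp$test) %in% c(8L, 9L))
    all3 <- c(sp$train, sp$validation, sp$test)
    expect_identical(sort(all3), seq_along(y))
    for (p in sp)
      expect_setequal(unique(y[p]), c("STS", "LTS"))
  }
  sp50 <- splitHoldout(y, testFrac = 0.5, seed = 3)
  expect_true(abs(length(sp50$test) - 21.5) <= 1)
  # validation is 40% of the train/validation pool
  pool <- length(sp50$train) + length(sp50$validation)
  expect_true(abs(length(sp50$validation) - 0.4 * pool) <= 1)
})

test_that("splits differ across repeats but are reproducible per repeat", {
  y <- cohortLabels()
  a <- splitHoldout(y, seed = 5, repeatIndex = 1)
  b <- splitHoldout(y, seed = 5, repeatIndex = 1)
  c <- splitHoldout(y, seed = 5, repeatIndex = 2)
  expect_identical(a, b)
  expect_false(identical(a$test, c$test))
})

test_that("a single-candidate grid is returned as-is", {
  withr::with_seed(31, {
    x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("STS", "LTS"), 20)
  })
  fit <- tuneAndTrain(x[1:30, ], y[1:30], x[31:40, ], y[31:40],
                      algorithm = "xgboost", depthGrid = 4L, nrounds = 10)
  expect_identical(fit$parameter, 4L)
})

test_that("perfect linear separation reaches validation F1 of 1", {
  withr::with_seed(32, {
    n <- 60
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- ifelse(x[, 1] > 0, "STS", "LTS")
  })
  for (alg in c("xgboost", "lasso", "ridge")) {
    fit <- tuneAndTrain(x[1:40, ], y[1:40], x[41:60, ], y[41:60],
                        algorithm = alg, depthGrid = c(2L, 4L),
                        nrounds = 30)
    expect_equal(fit$validationF1, 1,
                 tolerance = if (alg == "ridge") 0.12 else 1e-9)
  }
  expect_error(tuneAndTrain(x[1:5, ], rep("STS", 5), x[6:10, ], y[6:10]),
               "degenerate")
})

test_that("simple signals select shallow trees most of the time", {
  shallow <- 0
  for (s in 1:10) {
    withr::with_seed(400 + s, {
      n <- 80
      x <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
      y <- ifelse(x[, 1] + rnorm(n, sd = 0.3) > 0, "STS", "LTS")
    })
    fit <- tuneAndTrain(x[1:48, ], y[1:48], x[49:80, ], y[49:80],
                        algorithm = "xgboost",
                        depthGrid = c(2L, 4L, 6L, 10L, 20L), nrounds = 30,
                        seed = s)
    if (fit$parameter <= 6L) shallow <- shallow + 1
  }
  expect_gte(shallow, 8)
})

test_that("the repeated protocol produces the declared number of repeats and models", {
  withr::with_seed(33, {
    x <- matrix(rnorm(43 * 5), 43, 5,
                dimnames = list(sprintf("S%02d", 1:43), paste0("f", 1:5)))
  })
  y <- stats::setNames(cohortLabels(), rownames(x))
  res <- repeatedProtocol(x, y, nRepeats = 10, depthGrid = c(2L, 4L),
                          nrounds = 10, seed = 2)
  expect_equal(nrow(res$perRepeat), 10L)
  expect_equal(res$classifiersTrained, 10L)
  expect_length(res$models, 10L)
  expect_equal(unname(res$means["F1"]), mean(res$perRepeat$F1, na.rm = TRUE))
})

test_that("label permutation drives test AUC to chance", {
  withr::with_seed(34, {
    x <- matrix(rnorm(43 * 6), 43, 6,
                dimnames = list(sprintf("S%02d", 1:43), paste0("f", 1:6)))
    y <- stats::setNames(sample(cohortLabels()), rownames(x))
  })
  res <- repeatedProtocol(x, y, nRepeats = 40, depthGrid = c(2L, 4L),
                          nrounds = 20, seed = 4)
  expect_gte(unname(res$means["AUC"]), 0.3)
  expect_lte(unname(res$means["AUC"]), 0.7)
})

test_that("a planted informative feature dominates the importance ranking", {
  withr::with_seed(35, {
    x <- matrix(rnorm(43 * 6), 43, 6,
                dimnames = list(sprintf("S%02d", 1:43), paste0("f", 1:6)))
    y <- stats::setNames(cohortLabels(), rownames(x))
    x[, "f3"] <- ifelse(y == "STS", 1.5, -1.5) + rnorm(43, sd = 0.3)
  })
  res <- repeatedProtocol(x, y, nRepeats = 25, depthGrid = c(2L, 4L),
                          nrounds = 20, seed = 6)
  imp <- aggregateImportance(res$models, res$featureNames)
  expect_identical(imp$feature[1], "f3")
  expect_true(all(imp$selectionCount <= 25L))
  expect_true(all(is.na(imp$meanGain) | imp$meanGain >= 0))
  never <- imp[imp$selectionCount == 0, ]
  expect_true(all(is.na(never$meanGain)))
})

test_that("SMOTE inside the protocol touches only the training partition", {
  withr::with_seed(36, {
    x <- matrix(rnorm(43 * 4), 43, 4,
                dimnames = list(sprintf("S%02d", 1:43), paste0("f", 1:4)))
  })
  y <- stats::setNames(cohortLabels(), rownames(x))
  res <- repeatedProtocol(x, y, nRepeats = 5, depthGrid = 2L, nrounds = 10,
                          smoteRatio = "1:1", seed = 8)
  expect_equal(nrow(res$perRepeat), 5L)
  # direct check of the leakage contract at the split level
  sp <- splitHoldout(y, seed = 8, repeatIndex = 1)
  expect_length(intersect(sp$test, c(sp$train, sp$validation)), 0)
})

test_that("cell-type driving accounts for every trained classifier", {
  withr::with_seed(37, {
    xs <- lapply(1:3, function(i) {
      m <- matrix(rnorm(43 * 3), 43, 3,
                  dimnames = list(sprintf("S%02d", 1:43), paste0("f", 1:3)))
      m
    })
    names(xs) <- c("B", "NK", "Monocytes")
  })
  y <- stats::setNames(cohortLabels(), sprintf("S%02d", 1:43))
  res <- runCellTypeModels(xs, y, nRepeats = 5, depthGrid = 2L,
                           nrounds = 5, seed = 1)
  expect_equal(res$classifiersTrained, 15L)
  expect_equal(nrow(res$meanMetrics), 3L)
})

test_that("median stratification splits around the cohort median with ties low", {
  g <- stratifyByMedian(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(unname(g), c("low", "low", "high", "high"))
  g2 <- stratifyByMedian(c(1, 2, 3))          # 2 equals the median
  expect_identical(unname(g2), c("low", "low", "high"))
  expect_identical(unname(stratifyByMedian(log(c(1, 2, 3) + 1))),
                   unname(g2))                 # rank-based
  expect_error(stratifyByMedian(rep(2, 5)), "identical")
  expect_error(stratifyByMedian(3), "at least 2")
})
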