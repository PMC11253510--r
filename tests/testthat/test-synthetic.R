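test_that("generation is bit-identical for the same spec and seed", {
  spec <- syntheticSpec(nCellTypes = 3, cellsPerType = 300, nSTS = 3,
                        nLTS = 2, cellsPerSample = 300, seed = 5)
  expect_identical(exprValues(generateReference(spec)),
                   exprValues(generateReference(spec)))
  a <- suppressWarnings(generateCohort(spec))
  b <- suppressWarnings(generateCohort(spec))
  expect_identical(exprValues(a$expression), exprValues(b$expression))
  expect_identical(a$survival, b$survival)
  spec2 <- syntheticSpec(nCellTypes = 3, cellsPerType = 300, nSTS = 3,
                         nLTS = 2, cellsPerSample = 300, seed = 6)
  c2 <- suppressWarnings(generateCohort(spec2))
  expect_false(identical(exprValues(c2$expression),
                         exprValues(a$expression)))
})

test_that("the reference has the requested bookkeeping", {
  spec <- syntheticSpec(cellsPerType = 1000, seed = 7)
  ref <- generateReference(spec)
  expect_equal(nCells(ref), 7000L)
  cnt <- cellTypeCounts(ref)
  expect_length(cnt, 7L)
  expect_true(all(cnt == 1000L))
  expect_true(all(cnt >= 300L))
})

test_that("zero within-type spread reproduces the profiles exactly", {
  spec <- syntheticSpec(nCellTypes = 3, cellsPerType = 300,
                        withinTypeSd = 0, seed = 8)
  ref <- generateReference(spec)
  m <- exprValues(ref)[, spec$backboneMarkers]
  for (ty in spec$cellTypes) {
    rows <- m[cellLabels(ref) == ty, , drop = FALSE]
    expect_true(all(abs(sweep(rows, 2, spec$typeProfiles[ty, ])) < 1e-12))
  }
})

test_that("type profiles respect the pairwise cosine separation cap", {
  for (s in 1:5) {
    spec <- syntheticSpec(seed = s)
    p <- spec$typeProfiles
    norms <- sqrt(rowSums(p^2))
    cosines <- (p %*% t(p)) / outer(norms, norms)
    diag(cosines) <- 0
    expect_lte(max(cosines), 0.7)
  }
  expect_error(syntheticSpec(nCellTypes = 40, backboneDim = 2,
                             separationCap = 0.1),
               "could not draw")
})

test_that("cohorts have the configured group sizes and lawful survival times", {
  spec <- syntheticSpec(nCellTypes = 3, cellsPerSample = 300, seed = 9)
  coh <- suppressWarnings(generateCohort(spec))
  expect_equal(sum(coh$survival$group == "STS"), 28L)
  expect_equal(sum(coh$survival$group == "LTS"), 15L)
  expect_true(all(coh$survival$survival_months[coh$survival$group ==
                                                 "LTS"] >= 60))
  expect_true(all(coh$survival$survival_months[coh$survival$group ==
                                                 "STS"] < 60))
  # per-sample cell counts and labels reconcile
  expect_equal(nCells(coh$expression), 43L * 300L)
  expect_length(cellLabels(coh$expression), nCells(coh$expression))
  expect_setequal(unique(sampleIds(coh$expression)),
                  coh$survival$sample_id)
})

test_that("a planted dependency shifts mean DREMI between survivor groups", {
  pp <- list(list(cellType = "B", x = "pAxl", y = "pNFkB", betaSTS = 2,
                  betaLTS = 0, noiseSd = 0.2))
  spec <- syntheticSpec(nCellTypes = 3, signalingDim = 3,
                        cellsPerSample = 700, abundanceConcentration = 10,
                        plantedPairs = pp, seed = 10)
  coh <- generateCohort(spec)
  f <- dremiPairFeatures(coh$expression, "B", spec$signalingMarkers)
  v <- featureValues(f)
  g <- stats::setNames(coh$survival$group,
                       coh$survival$sample_id)[rownames(v)]
  expect_gt(mean(v[g == "STS", "pAxl->pNFkB"]),
            mean(v[g == "LTS", "pAxl->pNFkB"]) + 0.5)
})

test_that("planted pairs are validated against the panels", {
  bad <- list(list(cellType = "B", x = "CD3", y = "pNFkB", betaSTS = 1,
                   betaLTS = 0))
  expect_error(syntheticSpec(plantedPairs = bad), "signaling panel")
  bad2 <- list(list(cellType = "Granulocytes", x = "pAxl", y = "pNFkB",
                    betaSTS = 1, betaLTS = 0))
  expect_error(syntheticSpec(plantedPairs = bad2), "not in the generated")
})

test_that("the truth table matches the generators and round-trips JSON", {
  pp <- list(list(cellType = "B", x = "pAxl", y = "pNFkB", betaSTS = 2,
                  betaLTS = 0, noiseSd = 0.2))
  spec <- syntheticSpec(nCellTypes = 3, cellsPerSample = 300,
                        plantedPairs = pp, seed = 11)
  tt <- truthTable(spec)
  expect_length(tt$plantedPairs, 1L)
  expect_equal(tt$plantedPairs[[1]]$effectSize, 2)
  expect_identical(tt$cellTypes, spec$cellTypes)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(tt, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$nSTS, 28L)
  expect_equal(back$plantedPairs$x, "pAxl")
})

test_that("scarce per-sample cells trigger the downstream masking warning", {
  expect_warning(generateCohort(syntheticSpec(nCellTypes = 7,
                                              cellsPerSample = 350,
                                              nSTS = 2, nLTS = 2,
                                              seed = 12)),
                 "masked")
})
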