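test_that("gene-set generator plants block overlap and respects the size floor", {
  gs <- generateGeneSets(6, sizeRange = c(12, 12), nBlocks = 2,
                         coreFraction = 0.5, seed = 11)
  sets <- geneSets(gs)
  blocks <- split(names(sets), setCategories(gs))
  expect_equal(lengths(blocks), c(block01 = 3L, block02 = 3L))
  for (b in blocks) {
    for (i in seq_along(b)) for (j in seq_len(i - 1))
      expect_gte(jaccardOracle(sets[[b[i]]], sets[[b[j]]]), 0.3)
  }
  for (a in blocks[[1]]) for (b in blocks[[2]])
    expect_identical(jaccardOracle(sets[[a]], sets[[b]]), 0)

  expect_error(generateGeneSets(5, sizeRange = c(5, 10)), "below 6")
  single <- generateGeneSets(1, seed = 2)
  expect_equal(length(single), 1L)
})

test_that("generators are byte-deterministic under a fixed seed", {
  gs1 <- generateGeneSets(10, seed = 5)
  gs2 <- generateGeneSets(10, seed = 5)
  expect_identical(geneSets(gs1), geneSets(gs2))

  a <- generateStudy(gs1, nCompounds = 12, nDifferential = 3, seed = 9)
  b <- generateStudy(gs1, nCompounds = 12, nDifferential = 3, seed = 9)
  expect_identical(exprsMatrix(a$study), exprsMatrix(b$study))
  expect_identical(a$truth@toxFactor, b$truth@toxFactor)

  da <- generateDescriptors(a$study, a$truth, nDescriptors = 15, nLinked = 2,
                            seed = 4)
  db <- generateDescriptors(b$study, b$truth, nDescriptors = 15, nLinked = 2,
                            seed = 4)
  expect_identical(descriptorValues(da$descriptors),
                   descriptorValues(db$descriptors))
  expect_identical(da$truth@triples, db$truth@triples)
})

test_that("study generator enforces its preconditions and planted toxic count", {
  gs <- generateGeneSets(8, seed = 1)
  expect_error(generateStudy(gs, nReps = 1), "nReps")
  expect_error(generateStudy(gs, fracToxic = 0), "fracToxic")
  expect_error(generateStudy(gs, fracToxic = 1), "fracToxic")

  res <- generateStudy(gs, nCompounds = 88, fracToxic = 22 / 88, nReps = 3,
                       nDifferential = 4, seed = 13)
  expect_equal(sum(res$truth@toxicity == "toxic"), 22L)
  expect_equal(sum(toxicityLabels(res$study) == "toxic"), 22L)
  cd <- sampleMeta(res$study)
  expect_equal(sum(cd$role == "treated"), 88L * 3L)
  expect_equal(sum(cd$role == "control"), 88L * 3L)
})

test_that("planted toxicity-factor shift matches the requested effect size", {
  gs <- generateGeneSets(10, seed = 2)
  res <- generateStudy(gs, nCompounds = 60, fracToxic = 0.3, effectSize = 2,
                       nDifferential = 5, seed = 21)
  t <- res$truth@toxFactor
  tox <- res$truth@toxicity == "toxic"
  diff <- mean(t[tox]) - mean(t[!tox])
  se <- sqrt(1 / sum(tox) + 1 / sum(!tox))   # unit residual sd by design
  expect_lt(abs(diff - 2), 3 * se)
})

test_that("on noiseless data pathway PC2 recovers the planted factor", {
  gs <- generateGeneSets(6, sizeRange = c(12, 16), nBlocks = 6,
                         coreFraction = 0, seed = 3)  # disjoint sets
  res <- generateStudy(gs, nCompounds = 60, noiseSd = 0, effectSize = 3,
                       nDifferential = 2, seed = 17)
  # rank-2 noiseless submatrices: a 0.95 variance target forces both factor
  # components to be retained so the recovery question is well-posed
  ix <- suppressWarnings(computePathwayIndices(res$study, gs,
                                               varianceTarget = 0.95))
  cd <- sampleMeta(res$study)
  for (pw in res$truth@differential) {
    sc <- pathwayScores(ix, pw)
    f2 <- ifelse(cd$role == "treated",
                 res$truth@factor2[cd$compound_id, pw], 0)
    expect_gt(abs(cor(sc[rownames(cd), 2], f2)), 0.99)
  }
})

test_that("descriptor generator plants exact and null triples as configured", {
  gs <- generateGeneSets(8, seed = 1)
  res <- generateStudy(gs, nCompounds = 40, nDifferential = 4, seed = 5)
  expect_error(generateDescriptors(res$study, res$truth, linkStrength = 1.5),
               "linkStrength")
  expect_error(generateDescriptors(res$study, res$truth, nDescriptors = 8),
               "at least 9")
  expect_error(generateDescriptors(res$study, res$truth, nLinked = 6),
               "differential")

  # linkStrength 1: the true triple interpolates the factor exactly
  de <- generateDescriptors(res$study, res$truth, nDescriptors = 20,
                            linkStrength = 1, nLinked = 3, seed = 8)
  for (pw in de$truth@linked) {
    y <- de$truth@factor2[compoundIds(res$study), pw]
    m <- fitEq1(y, de$descriptors, de$truth@triples[[pw]])
    expect_gt(m@trainR2, 1 - 1e-9)
    est <- m@coefficients
    names(est) <- names(de$truth@coefficients[[pw]])
    expect_lt(max(abs(est - de$truth@coefficients[[pw]])), 1e-6)
  }

  # linkStrength 0: the true triple has no out-of-sample predictive value
  de0 <- generateDescriptors(res$study, res$truth, nDescriptors = 20,
                             linkStrength = 0, nLinked = 3, seed = 8)
  cvs <- vapply(de0$truth@linked, function(pw)
    cvR2(de0$truth@factor2[compoundIds(res$study), pw], de0$descriptors,
         de0$truth@triples[[pw]], seed = 1), numeric(1))
  expect_lt(max(cvs), 0.5)
})

test_that("planted interaction terms carry at least half the explained variance", {
  gs <- generateGeneSets(10, seed = 6)
  res <- generateStudy(gs, nCompounds = 60, nDifferential = 6, seed = 7)
  de <- generateDescriptors(res$study, res$truth, nDescriptors = 30,
                            linkStrength = 0.9, nLinked = 6, seed = 9)
  shares <- vapply(de$truth@linked, function(pw) {
    y <- de$truth@factor2[compoundIds(res$study), pw]
    m <- fitEq1(y, de$descriptors, de$truth@triples[[pw]])
    interactionShare(m, y, de$descriptors)
  }, numeric(1))
  expect_gte(median(shares), 0.5)
})

test_that("synthetic inputs round-trip through the interchange formats", {
  gs <- generateGeneSets(6, seed = 1)
  res <- generateStudy(gs, nCompounds = 14, fracToxic = 3 / 14,
                       nDifferential = 2, seed = 2)
  de <- generateDescriptors(res$study, res$truth, nDescriptors = 12,
                            nLinked = 2, seed = 3)
  dir <- withr::local_tempdir()
  writeSyntheticInputs(res$study, gs, de$descriptors, de$truth, dir)
  back <- readExpressionStudy(file.path(dir, "expression.tsv"),
                              file.path(dir, "samples.tsv"))
  expect_identical(exprsMatrix(back), exprsMatrix(res$study))
  backD <- readDescriptorMatrix(file.path(dir, "descriptors.tsv"),
                                file.path(dir, "descriptor_groups.tsv"))
  expect_identical(descriptorValues(backD), descriptorValues(de$descriptors))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$linked), de$truth@linked)
  expect_equal(truth$seed, 2L)
})
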