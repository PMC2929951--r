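test_that("pathway targets average treated replicate scores per compound", {
  study <- tinyStudy(nGenes = 6, nCompounds = 2, nReps = 3)
  cd <- sampleMeta(study)
  sc <- matrix(0, nrow(cd), 2, dimnames = list(rownames(cd), c("PC1", "PC2")))
  sc[cd$compound_id == "C01" & cd$role == "treated", "PC2"] <- c(1, 2, 3)
  sc[cd$compound_id == "C02" & cd$role == "treated", "PC2"] <- c(5, 5, 8)
  ix <- new("PathwayIndexSet", scores = list(PW1 = sc),
            loadings = list(PW1 = matrix(1, 6, 2)),
            varFrac = list(PW1 = c(0.7, 0.2)),
            cumVar = c(PW1 = 0.9), nGenes = c(PW1 = 6L),
            excluded = data.frame(), belowTarget = character(),
            params = list(maxPcs = 2), sampleIds = rownames(cd))
  tg <- pathwayTargets(ix, study, whichPc = 2)
  expect_equal(tg["C01", "PW1"], 2.0)
  expect_equal(tg["C02", "PW1"], 6.0)

  # pathways without the requested PC are dropped and reported
  ix1 <- ix
  ix1@scores$PW1 <- sc[, 1, drop = FALSE]
  tg1 <- pathwayTargets(ix1, study, whichPc = 2)
  expect_equal(ncol(tg1), 0L)
  expect_equal(attr(tg1, "dropped"), "PW1")
})

test_that("noiseless targets recover the planted coefficients exactly", {
  pd <- plantedTripleData(n = 40, nd = 10, r2 = 1, seed = 2)
  m <- fitEq1(pd$y, pd$D, pd$triple)
  expect_equal(m@trainR2, 1, tolerance = 1e-12)
  expect_lt(max(abs(m@coefficients - pd$coefs)), 1e-6)

  # near-noiseless recovery stays within 1e-4
  withr::with_seed(5, {
    D <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a1", "a2", "a3")))
    coefs <- rnorm(7)
    y <- as.vector(eq1DesignOracle(D) %*% coefs) + rnorm(40, 0, 1e-6)
    m2 <- fitEq1(y, D, colnames(D))
    expect_lt(max(abs(m2@coefficients - coefs)), 1e-4)
  })
})

test_that("least squares matches the normal-equations oracle", {
  withr::with_seed(8, for (i in 1:100) {
    n <- sample(10:40, 1)
    D <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    m <- fitEq1(y, D, c(1, 2, 3))
    expect_equal(unname(m@coefficients), normalEqOracle(y, D),
                 tolerance = 1e-8)
  })
})

test_that("degenerate fits behave as specified", {
  D <- matrix(rnorm(30), 10, 3)
  m <- fitEq1(rep(2.5, 10), D, c(1, 2, 3))
  expect_equal(m@trainR2, 0)
  expect_equal(unname(m@coefficients[-1]), rep(0, 6))
  expect_equal(unname(m@coefficients[1]), 2.5)

  collinear <- cbind(D[, 1], D[, 1], D[, 2])
  expect_error(fitEq1(rnorm(10), collinear, c(1, 2, 3)), "collinear")
  expect_error(fitEq1(rnorm(7), D[1:7, ], c(1, 2, 3)), "at least 8")
  expect_error(fitEq1(rnorm(10), D, c(1, 1, 2)), "distinct")
})

test_that("cross-validated R2 behaves at the signal and null extremes", {
  pd <- plantedTripleData(n = 60, nd = 6, r2 = 1, seed = 3)
  expect_gt(cvR2(pd$y, pd$D, pd$triple, seed = 1), 0.99)

  # pure-noise target: random triples have no generalization power
  withr::with_seed(9, {
    D <- matrix(rnorm(60 * 12), 60, 12)
    y <- rnorm(60)
    cvs <- vapply(1:50, function(i)
      cvR2(y, D, sample(12, 3), seed = i), numeric(1))
    expect_lte(median(cvs), 0)
  })

  # deterministic given the seed; error when a fold undercuts the fit
  expect_identical(cvR2(pd$y, pd$D, pd$triple, seed = 7),
                   cvR2(pd$y, pd$D, pd$triple, seed = 7))
  expect_error(cvR2(rnorm(9), matrix(rnorm(27), 9, 3), 1:3, k = 5, seed = 1),
               "fewer than 8")
})

test_that("CV R2 does not beat training R2 on average", {
  gaps <- withr::with_seed(12, vapply(1:30, function(i) {
    D <- matrix(rnorm(30 * 3), 30, 3)
    y <- rnorm(30)
    m <- fitEq1(y, D, c(1, 2, 3))
    m@trainR2 - cvR2(y, D, c(1, 2, 3), seed = i)
  }, numeric(1)))
  expect_gt(mean(gaps), 0)
})

test_that("GA search equals exhaustive enumeration on small instances", {
  agree <- 0
  for (s in 1:10) {
    pd <- plantedTripleData(n = 36, nd = 10, r2 = 0.7, seed = 100 + s)
    popn <- gaSearch(pd$y, pd$D, nRuns = 3, population = 20, generations = 25,
                     seed = s)
    best <- populationModels(popn)[[1]]
    allTriples <- utils::combn(10, 3)
    exhaustive <- apply(allTriples, 2, function(tr)
      tryCatch(gaObjective(popn, pd$y, pd$D, tr), error = function(e) -Inf))
    if (abs(best@cvR2 - max(exhaustive)) < 1e-9) agree <- agree + 1
  }
  expect_gte(agree, 9)
})

test_that("GA recovers a strongly linked planted triple as the top model", {
  hits <- 0
  for (s in 1:10) {
    pd <- plantedTripleData(n = 60, nd = 20, r2 = 0.9, seed = 200 + s)
    popn <- gaSearch(pd$y, pd$D, nRuns = 6, population = 24, generations = 40,
                     seed = s)
    top <- populationModels(popn)[[1]]
    if (identical(sort(top@triple), sort(pd$triple))) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("pure-noise targets are not flagged as PCF-linked", {
  flagged <- 0
  for (s in 1:10) {
    withr::with_seed(300 + s, {
      D <- matrix(rnorm(60 * 15), 60, 15)
      y <- rnorm(60)
    })
    popn <- gaSearch(y, D, nRuns = 4, population = 20, generations = 25,
                     threshold = 0.5, seed = s)
    if (isFlagged(popn)) flagged <- flagged + 1
  }
  expect_lte(flagged, 1)
})

test_that("flagging is monotone in the fitness threshold", {
  pd <- plantedTripleData(n = 40, nd = 12, r2 = 0.6, seed = 77)
  thresholds <- c(0.2, 0.5, 0.9)
  flags <- vapply(thresholds, function(th)
    isFlagged(gaSearch(pd$y, pd$D, nRuns = 2, population = 16,
                       generations = 15, threshold = th, seed = 5)),
    logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("GA populations are deterministic and sorted by fitness", {
  pd <- plantedTripleData(n = 40, nd = 12, r2 = 0.8, seed = 55)
  p1 <- gaSearch(pd$y, pd$D, nRuns = 3, population = 16, generations = 15,
                 seed = 9)
  p2 <- gaSearch(pd$y, pd$D, nRuns = 3, population = 16, generations = 15,
                 seed = 9)
  expect_identical(lapply(populationModels(p1), slot, "triple"),
                   lapply(populationModels(p2), slot, "triple"))
  cv <- vapply(populationModels(p1), slot, numeric(1), "cvR2")
  expect_true(all(diff(cv) <= 1e-12))
})

test_that("interaction share isolates the interaction contribution", {
  withr::with_seed(21, {
    D <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("X1", "X2", "X3")))
    yMain <- as.vector(eq1DesignOracle(D) %*% c(1, 0.8, -0.6, 0.9, 0, 0, 0))
    mMain <- fitEq1(yMain, D, c(1, 2, 3))
    expect_lt(interactionShare(mMain, yMain, D), 0.01)

    yInter <- as.vector(eq1DesignOracle(D) %*% c(0, 0, 0, 0, 1.2, -0.8, 0.7))
    mInter <- fitEq1(yInter, D, c(1, 2, 3))
    expect_gt(interactionShare(mInter, yInter, D), 0.95)

    # constant target: share undefined
    mConst <- fitEq1(rep(1, 80), D, c(1, 2, 3))
    expect_true(is.na(interactionShare(mConst, rep(1, 80), D)))
  })
})

test_that("the descriptor-group network counts pathway-level pair support", {
  groups <- setNames(c("A", "A", "B", "C"), c("D1", "D2", "D3", "D4"))
  dm <- DescriptorMatrix(matrix(rnorm(40), 10, 4,
    dimnames = list(sprintf("C%02d", 1:10), names(groups))), groups)
  popn <- fakePopulation("PW1", list(c("D1", "D2", "D3")), list(0.8))
  net <- descriptorGroupNetwork(list(popn), dm)
  e <- net$edges
  expect_equal(nrow(e), 2L)
  expect_equal(e$weight[e$group1 == "A" & e$group2 == "A"], 1)
  expect_equal(e$weight[e$group1 == "A" & e$group2 == "B"], 1)

  # empty population -> empty graph
  netEmpty <- descriptorGroupNetwork(list(), dm)
  expect_equal(nrow(netEmpty$edges), 0L)
  expect_equal(igraph::gorder(netEmpty$graph), 0L)
})

test_that("a dominant group pair accumulates the maximum edge weight", {
  groups <- setNames(c("ET-state Indices", "Geometrical descriptors",
                       "RDF descriptors", "WHIM descriptors",
                       "GSFRAG Descriptor"),
                     c("D1", "D2", "D3", "D4", "D5"))
  dm <- DescriptorMatrix(matrix(rnorm(50), 10, 5,
    dimnames = list(sprintf("C%02d", 1:10), names(groups))), groups)
  pops <- c(
    lapply(1:11, function(i)
      fakePopulation(sprintf("PW%02d", i), list(c("D1", "D2", "D3")), list(0.7))),
    lapply(12:19, function(i)
      fakePopulation(sprintf("PW%02d", i), list(c("D3", "D4", "D5")), list(0.7))))
  net <- descriptorGroupNetwork(pops, dm)
  e <- net$edges
  w <- e$weight[e$group1 == "ET-state Indices" &
                  e$group2 == "Geometrical descriptors"]
  expect_equal(w, 11)
  expect_equal(max(e$weight), 11)
})
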