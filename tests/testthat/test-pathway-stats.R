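test_that("Hotelling T2 is zero for equal means and matches its F transform", {
  A <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 4, 2)
  res <- hotellingT2(A, A)
  expect_equal(res$T2, 0)
  expect_equal(res$p.value, 1)

  withr::with_seed(7, {
    A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(10, 1), 5, 2)
    r <- hotellingT2(A, B)
    expect_equal(r$F, r$T2 * (10 - 2 - 1) / (2 * (10 - 2)), tolerance = 1e-12)
    expect_equal(r$p.value, pf(r$F, 2, 7, lower.tail = FALSE), tolerance = 1e-12)
  })
})

test_that("at p = 1 the T2 equals the squared pooled-variance t statistic", {
  withr::with_seed(11, for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5, 0.8)
    r <- hotellingT2(matrix(x), matrix(y))
    t <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$T2, unname(t$statistic)^2, tolerance = 1e-8)
    expect_equal(r$p.value, t$p.value, tolerance = 1e-8)
  })
})

test_that("T2 is invariant under a common affine change of basis", {
  withr::with_seed(13, for (i in 1:10) {
    A <- matrix(rnorm(12), 6, 2); B <- matrix(rnorm(12, 0.5), 6, 2)
    M <- matrix(rnorm(4), 2, 2)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(4), 2, 2)
    shift <- rnorm(2)
    tA <- sweep(A %*% M, 2, shift, `+`); tB <- sweep(B %*% M, 2, shift, `+`)
    expect_equal(hotellingT2(tA, tB)$T2, hotellingT2(A, B)$T2,
                 tolerance = 1e-8)
  })
})

test_that("T2 matches a MANOVA Hotelling-Lawley oracle", {
  withr::with_seed(17, for (i in 1:25) {
    p <- sample(1:3, 1)
    A <- matrix(rnorm(7 * p), 7, p); B <- matrix(rnorm(8 * p, 0.5), 8, p)
    expect_equal(hotellingT2(A, B)$T2, hotellingManovaOracle(A, B),
                 tolerance = 1e-8)
  })
})

test_that("degenerate T2 inputs are handled as specified", {
  expect_error(hotellingT2(matrix(1:3, 1), matrix(4:6, 1)), "insufficient")
  # duplicated column -> singular pooled covariance -> ridge fallback
  withr::with_seed(19, {
    x <- rnorm(6); y <- rnorm(6, 1)
    A <- cbind(x, x); B <- cbind(y, y)
    r <- hotellingT2(A, B)
    expect_true(r$ridged)
    expect_true(is.finite(r$T2) && r$T2 >= 0)
  })
})

test_that("BH adjustment reproduces the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 8 / 300, 0.8), tolerance = 1e-12)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(23, for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # rank monotone
  })
})

test_that("treated samples identical to controls give a zero perturbation row", {
  gs <- generateGeneSets(5, seed = 2)
  res <- generateStudy(gs, nCompounds = 6, fracToxic = 1 / 3,
                       nDifferential = 2, seed = 3)
  m <- exprsMatrix(res$study)
  cd <- sampleMeta(res$study)
  # make compound C001's treated samples copies of its controls
  tr <- rownames(cd)[cd$compound_id == "C001" & cd$role == "treated"]
  ct <- rownames(cd)[cd$compound_id == "C001" & cd$role == "control"]
  m[, tr] <- m[, ct]
  dup <- ExpressionStudy(m, cd)
  ix <- suppressWarnings(computePathwayIndices(dup, gs))
  pert <- perturbationIndex(ix, dup)
  expect_equal(unname(perturbationValues(pert)["C001", ]),
               rep(0, length(retainedPathways(ix))), tolerance = 1e-8)
})

test_that("a planted perturbed pathway dominates toxic drugs' rows", {
  # the only planted perturbation is the differential pathway's factor: no
  # dose factor and no specific activity elsewhere, so the row maximum is a
  # well-posed recovery target
  hits <- 0; nSeeds <- 15
  for (s in seq_len(nSeeds)) {
    gs <- generateGeneSets(12, nBlocks = 12, coreFraction = 0, seed = s)
    res <- generateStudy(gs, nCompounds = 16, fracToxic = 0.25,
                         effectSize = 3, nDifferential = 1, factor1Sd = 0,
                         nullFactorSd = 0, seed = 100 + s)
    ix <- suppressWarnings(computePathwayIndices(res$study, gs))
    pert <- perturbationValues(perturbationIndex(ix, res$study))
    toxic <- names(res$truth@toxicity)[res$truth@toxicity == "toxic"]
    planted <- res$truth@differential
    frac <- mean(vapply(toxic, function(d)
      names(which.max(pert[d, ])) == planted, logical(1)))
    if (frac >= 0.5) hits <- hits + 1
  }
  expect_gte(hits / nSeeds, 0.9)
})

test_that("drug clustering separates opposite perturbation profiles", {
  base <- c(10, 10, 10, 1, 1, 1)
  profiles <- rbind(base + 0.1, base + 0.2, base - 0.1,
                    rev(base) + 0.1, rev(base) - 0.2, rev(base))
  rownames(profiles) <- paste0("drug", 1:6)
  colnames(profiles) <- paste0("PW", 1:6)
  pm <- new("PerturbationMatrix", t2 = profiles,
            issues = data.frame(), params = list())
  cl <- clusterDrugs(pm)
  expect_equal(cl$distance, "correlation")
  cut <- cutree(cl$hclust, 2)
  expect_equal(length(unique(cut[1:3])), 1L)
  expect_equal(length(unique(cut[4:6])), 1L)
  expect_false(cut[1] == cut[4])

  # identical rows merge at height zero
  ident <- pm
  ident@t2[2, ] <- ident@t2[1, ]
  cl2 <- clusterDrugs(ident)
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)

  # constant row: correlation undefined -> Euclidean fallback with warning
  flat <- pm
  flat@t2[1, ] <- 2
  expect_warning(cl3 <- clusterDrugs(flat), "Euclidean")
  expect_equal(cl3$distance, "euclidean")
})

test_that("most toxic drugs co-cluster at study scale with strong effects", {
  gs <- generateGeneSets(30, nBlocks = 3, seed = 41)
  res <- generateStudy(gs, nCompounds = 88, fracToxic = 22 / 88,
                       effectSize = 4, nDifferential = 10, seed = 41)
  ix <- suppressWarnings(computePathwayIndices(res$study, gs))
  pert <- perturbationIndex(ix, res$study)
  cl <- clusterDrugs(pert)
  cut <- cutree(cl$hclust, 2)
  toxic <- names(res$truth@toxicity)[res$truth@toxicity == "toxic"]
  share <- max(vapply(unique(cut), function(k)
    mean(cut[toxic] == k), numeric(1)))
  expect_gte(share, 0.8)
})

test_that("differential testing wires T2, BH and selection together", {
  gs <- generateGeneSets(12, nBlocks = 2, seed = 51)
  res <- generateStudy(gs, nCompounds = 20, fracToxic = 0.3, effectSize = 3,
                       nDifferential = 6, seed = 51)
  ix <- suppressWarnings(computePathwayIndices(res$study, gs))
  dr <- differentialPathways(ix, res$study, fdrLevel = 0.01)
  tab <- resultTable(dr)
  expect_equal(nrow(tab), length(retainedPathways(ix)))
  expect_equal(tab$q_value, bhAdjust(tab$p_value))
  expect_setequal(selectedPathways(dr), tab$pathway[tab$q_value < 0.01])
  expect_true(all(tab$T2 >= 0))
  # planted pathways carry the signal on PC2 rather than PC1
  planted <- tab[tab$pathway %in% res$truth@differential, ]
  expect_gt(mean(abs(planted$t_pc2)), mean(abs(planted$t_pc1)))

  # a class without treated samples is an error
  cd <- sampleMeta(res$study)
  cd$toxicity[cd$toxicity == "toxic"] <- "nontoxic"
  oneClass <- ExpressionStudy(exprsMatrix(res$study), cd)
  expect_error(differentialPathways(ix, oneClass), "classes")
})
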