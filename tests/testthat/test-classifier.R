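sepData <- function(n = 60, d = 3, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n / 2 * d), n / 2, d),
               matrix(rnorm(n / 2 * d, gap), n / 2, d))
    colnames(X) <- paste0("F", seq_len(d))
    rownames(X) <- sprintf("C%03d", seq_len(n))
    list(X = X, labels = rep(c("nontoxic", "toxic"), each = n / 2))
  })
}

test_that("MLHD separates well-separated Gaussian clouds perfectly", {
  sd <- sepData(gap = 6, seed = 2)
  m <- mlhdFit(sd$X, sd$labels)
  expect_equal(mean(predict(m, sd$X) == sd$labels), 1)
  expect_error(mlhdFit(sd$X, rep("toxic", 60)), "two classes")
  expect_error(mlhdFit(sd$X[1:6, ], sd$labels[c(1:3, 31:33)]), "d \\+ 2")
})

test_that("MLHD equals the closed-form equal-prior linear discriminant", {
  skip_if_not_installed("MASS")
  withr::with_seed(31, {
    X <- rbind(matrix(rnorm(40 * 2), 40, 2),
               matrix(rnorm(40 * 2, 1.2), 40, 2))
    colnames(X) <- c("F1", "F2")
    labels <- rep(c("a", "b"), each = 40)
    grid <- as.matrix(expand.grid(F1 = seq(-3, 4, 0.25),
                                  F2 = seq(-3, 4, 0.25)))
  })
  m <- mlhdFit(X, labels)
  ld <- MASS::lda(X, grouping = labels, prior = c(0.5, 0.5))
  expect_identical(predict(m, grid),
                   as.character(predict(ld, grid)$class))
})

test_that("MLHD predictions are invariant under common affine transforms", {
  sd <- sepData(gap = 2, seed = 7)
  M <- matrix(c(2, 0.5, -1, 1.5, 0.3, 0.2, 0, 1, 2), 3, 3)
  shift <- c(5, -3, 2)
  Xt <- sweep(sd$X %*% M, 2, shift, `+`)
  p1 <- predict(mlhdFit(sd$X, sd$labels), sd$X)
  p2 <- predict(mlhdFit(Xt, sd$labels), Xt)
  expect_identical(p1, p2)
})

test_that("label-permuted CV accuracy is at chance on balanced data", {
  sd <- sepData(n = 100, gap = 3, seed = 11)
  perm <- withr::with_seed(13, sample(sd$labels))
  acc <- pcflink:::mlhdCvAccuracy(sd$X, perm, k = 5, seed = 3)
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("feature split applies the linkage and correlation rules exactly", {
  withr::with_seed(17, {
    n <- 50
    D1 <- rnorm(n); D2 <- rnorm(n); D3 <- rnorm(n)
    D4 <- 0.9 * scale(D1)[, 1] + sqrt(1 - 0.81) * rnorm(n)  # r ~ 0.9 with D1
    D5 <- rnorm(n); D6 <- rnorm(n)
    v <- cbind(D1 = D1, D2 = D2, D3 = D3, D4 = D4, D5 = D5, D6 = D6)
    rownames(v) <- sprintf("C%02d", 1:n)
  })
  dm <- DescriptorMatrix(v, setNames(rep("RDF descriptors", 6), colnames(v)))
  popn <- fakePopulation("PW1", list(c("D1", "D2", "D3")), list(0.8))
  fs <- splitFeatures(dm, list(popn), corCutoff = 0.5)
  expect_setequal(fs@linked, c("D1", "D2", "D3"))
  expect_false("D4" %in% c(fs@linked, fs@uncorrelated))
  expect_setequal(fs@uncorrelated, c("D5", "D6"))
  # the emitted pair obeys the rule exhaustively
  cm <- abs(cor(v[, fs@uncorrelated], v[, fs@linked]))
  expect_true(all(cm < 0.5))
  expect_length(intersect(fs@linked, fs@uncorrelated), 0)

  noPass <- fakePopulation("PW1", list(c("D1", "D2", "D3")), list(0.2))
  expect_error(splitFeatures(dm, list(noPass)), "no PCF-linked")
})

test_that("feature-split bookkeeping scales to a 92 / 210 study-shape fixture", {
  withr::with_seed(19, {
    n <- 88
    linkedBlock <- matrix(rnorm(n * 92), n, 92)
    freeBlock <- matrix(rnorm(n * 210), n, 210)
    # remaining descriptors are noisy copies of linked ones -> excluded by
    # the correlation rule
    copies <- linkedBlock[, rep_len(1:92, 60)] +
      matrix(rnorm(n * 60, 0, 0.3), n, 60)
    v <- cbind(linkedBlock, freeBlock, copies)
    colnames(v) <- sprintf("D%04d", seq_len(ncol(v)))
    rownames(v) <- sprintf("C%03d", 1:n)
  })
  dm <- DescriptorMatrix(v, setNames(rep_len(c("RDF descriptors",
                                               "WHIM descriptors"),
                                             ncol(v)), colnames(v)))
  linkedIds <- colnames(v)[1:92]
  pops <- lapply(seq(1, 91, 3), function(i)
    fakePopulation(sprintf("PW%02d", i), list(linkedIds[i:(i + 2)]),
                   list(0.7)))
  fs <- splitFeatures(dm, pops, corCutoff = 0.5)
  expect_length(fs@linked, 92)
  expect_length(fs@uncorrelated, 210)
})

test_that("classifier GA finds informative features and is deterministic", {
  withr::with_seed(23, {
    n <- 60
    labels <- rep(c("toxic", "nontoxic"), c(20, 40))
    inf <- matrix(rnorm(n * 3), n, 3) + 2.2 * (labels == "toxic")
    noise <- matrix(rnorm(n * 9), n, 9)
    v <- cbind(inf, noise)
    colnames(v) <- sprintf("D%02d", seq_len(ncol(v)))
    rownames(v) <- sprintf("C%02d", 1:n)
  })
  dm <- DescriptorMatrix(v, setNames(rep("RDF descriptors", 12), colnames(v)))
  res <- gaClassifierSearch(dm, labels, colnames(v), nRuns = 8,
                            population = 14, generations = 12, seed = 3)
  expect_length(res$accuracies, 8)
  expect_gt(mean(res$accuracies), 0.85)
  # most selected features are the informative ones
  feats <- unlist(lapply(res$models, `[[`, "features"))
  expect_gte(mean(feats %in% c("D01", "D02", "D03")), 0.6)

  res2 <- gaClassifierSearch(dm, labels, colnames(v), nRuns = 8,
                             population = 14, generations = 12, seed = 3)
  expect_identical(res, res2)

  # uninformative subset: accuracy near the chance level of the CV rule
  resNull <- gaClassifierSearch(dm, labels, colnames(v)[4:12], nRuns = 5,
                                population = 14, generations = 10, seed = 4)
  expect_lt(mean(resNull$accuracies), 0.8)
})

test_that("subset comparison is symmetric and detects shifted distributions", {
  withr::with_seed(29, {
    a <- rnorm(100, 0.76, 0.05)
    b <- rnorm(100, 0.68, 0.05)
  })
  cmp <- compareSubsets(a, b)
  expect_lt(cmp$p.value, 0.001)
  expect_gt(cmp$difference, 0.05)
  rev <- compareSubsets(b, a)
  expect_equal(rev$p.value, cmp$p.value)
  expect_equal(rev$difference, -cmp$difference)

  same <- compareSubsets(a, a)
  expect_gt(same$p.value, 0.05)
  expect_error(compareSubsets(a[1:5], b), "at least 20")
})

test_that("the representative model takes the most frequent features", {
  models <- c(
    replicate(6, list(features = c("D1", "D2", "D3"), accuracy = 0.8),
              simplify = FALSE),
    replicate(2, list(features = c("D4", "D5", "D6"), accuracy = 0.6),
              simplify = FALSE))
  sd <- sepData(n = 60, d = 6, gap = 6, seed = 5)
  colnames(sd$X) <- paste0("D", 1:6)
  dm <- DescriptorMatrix(sd$X, setNames(rep("RDF descriptors", 6),
                                        colnames(sd$X)))
  rep <- representativeModel(list(models = models,
                                  settings = list(priors = "equal")),
                             dm, sd$labels)
  expect_setequal(rep$features, c("D1", "D2", "D3"))
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(sum(rep$confusion), 60)
  expect_equal(ncol(rep$pcaCoords), 3L)
})
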