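# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately use different code paths from the implementation.

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j
bhOracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(ps[i:n] * n / (i:n), 1))
  out <- numeric(n)
  out[ord] <- q
  out
}

# set-arithmetic Jaccard
jaccardOracle <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# Hotelling T2 via the Hotelling-Lawley trace of a one-way MANOVA:
# T2 = HL * (n + m - 2). At p = 1 the one-way ANOVA F equals the squared
# pooled t, which equals T2.
hotellingManovaOracle <- function(A, B) {
  Y <- rbind(as.matrix(A), as.matrix(B))
  grp <- factor(rep(c("A", "B"), c(nrow(A), nrow(B))))
  if (ncol(Y) == 1) {
    return(stats::anova(stats::lm(Y[, 1] ~ grp))[["F value"]][1])
  }
  fit <- stats::manova(Y ~ grp)
  hl <- summary(fit, test = "Hotelling-Lawley")$stats[1, "Hotelling-Lawley"]
  hl * (nrow(Y) - 2)
}

# normal-equations least squares for the Eq1 design
eq1DesignOracle <- function(D) {
  D <- as.matrix(D)
  cbind(1, D[, 1], D[, 2], D[, 3], D[, 1] * D[, 2], D[, 1] * D[, 3],
        D[, 2] * D[, 3])
}
normalEqOracle <- function(y, D) {
  X <- eq1DesignOracle(D)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# evaluate a triple with exactly the objective a gaSearch used (its stored
# training split and fold assignment)
gaObjective <- function(popn, y, descriptors, triple) {
  s <- popn@settings
  v <- if (methods::is(descriptors, "DescriptorMatrix"))
    descriptorValues(descriptors) else as.matrix(descriptors)
  cvR2(y[s$trainIdx], v[s$trainIdx, , drop = FALSE], triple,
       k = s$cvFolds, folds = s$folds)
}

# tiny valid study: nGenes x (2 compounds x nReps treated + controls)
tinyStudy <- function(nGenes = 10, nCompounds = 2, nReps = 3, seed = 42) {
  withr::with_seed(seed, {
    ids <- sprintf("g%02d", seq_len(nGenes))
    cols <- list(); meta <- list()
    for (c in seq_len(nCompounds)) {
      cid <- sprintf("C%02d", c)
      for (r in seq_len(nReps)) {
        cols[[sprintf("%s_T%d", cid, r)]] <- rnorm(nGenes, 5 + c)
        meta[[sprintf("%s_T%d", cid, r)]] <-
          c(cid, "treated", cid, if (c == 1) "toxic" else "nontoxic")
      }
      for (r in seq_len(nReps)) {
        cols[[sprintf("%s_C%d", cid, r)]] <- rnorm(nGenes, 5)
        meta[[sprintf("%s_C%d", cid, r)]] <- c(cid, "control", cid, "na")
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    md <- do.call(rbind, meta)
    meta <- data.frame(compound_id = md[, 1], role = md[, 2],
                       match_group = md[, 3], toxicity = md[, 4],
                       stringsAsFactors = FALSE)
    rownames(meta) <- colnames(m)
    ExpressionStudy(m, meta)
  })
}

# regression dataset with a planted descriptor triple (columns 1:3):
# y = a + b D1 + c D2 + d D3 + e D1 D2 + noise tuned to a target R2
plantedTripleData <- function(n = 60, nd = 20, r2 = 0.9, seed = 1) {
  withr::with_seed(seed, {
    D <- matrix(rnorm(n * nd), n, nd,
                dimnames = list(NULL, sprintf("D%03d", seq_len(nd))))
    coefs <- c(a = 0.1, b = 0.6, c = -0.5, d = 0.9, e = 1.4, f = 0, g = 0)
    signal <- eq1DesignOracle(D[, 1:3]) %*% coefs
    sigma <- sqrt(stats::var(as.vector(signal)) * (1 / r2 - 1))
    y <- as.vector(signal) + rnorm(n, 0, sigma)
    list(y = y, D = D, coefs = coefs, triple = colnames(D)[1:3])
  })
}

# a minimal ModelPopulation with hand-set triples/fitness, for network and
# feature-split bookkeeping tests
fakePopulation <- function(pathway, triples, cvR2s, threshold = 0.5) {
  models <- Map(function(tr, fit)
    new("Eq1Model", pathwayId = pathway, pcIndex = 2L, triple = tr,
        coefficients = stats::setNames(rep(0.1, 7), letters[1:7]),
        trainR2 = fit, cvR2 = fit, testR2 = fit, sigma2 = 0.1),
    triples, cvR2s)
  ord <- order(-unlist(cvR2s))
  new("ModelPopulation", pathwayId = pathway, models = models[ord],
      settings = list(threshold = threshold), seed = 1L,
      flagged = any(unlist(cvR2s) >= threshold))
}
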