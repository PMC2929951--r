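# Toxicity prediction from descriptor subsets: maximum-likelihood Gaussian
# discriminant (pooled covariance), GA feature selection with cross-validated
# accuracy, subset comparison, and representative-model reporting.

#' Fit a maximum-likelihood Gaussian discriminant
#'
#' Class-conditional Gaussian model with per-class means and a pooled
#' covariance; prediction assigns the class with the highest likelihood. With
#' equal priors (the default) this is the classic linear discriminant rule;
#' \code{priors = "empirical"} uses class frequencies. A singular pooled
#' covariance is ridge-regularized with \eqn{\lambda = 10^{-8} tr(S)/d}.
#'
#' @param features numeric compounds x d matrix.
#' @param labels factor or character class labels (>= 2 classes; each class
#'   needs at least d + 2 observations).
#' @param priors "equal" (default), "empirical", or a named numeric vector.
#' @return An \linkS4class{MLHDModel}.
#' @export
mlhdFit <- function(features, labels, priors = "equal") {
  X <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  d <- ncol(X)
  counts <- table(labels)
  if (any(counts < d + 2))
    stop("every class needs at least d + 2 = ", d + 2, " observations")
  means <- t(vapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                    numeric(d)))
  S <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- X[labels == cl, , drop = FALSE]
    S <- S + (nrow(Xc) - 1) * stats::cov(Xc)
  }
  S <- S / (nrow(X) - length(classes))
  ridged <- FALSE
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(S) < 1e-12) {
    lambda <- 1e-8 * sum(diag(S)) / d
    if (lambda <= 0) lambda <- 1e-8
    Sinv <- solve(S + diag(lambda, d))
    ridged <- TRUE
  }
  pr <- if (identical(priors, "equal"))
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  else if (identical(priors, "empirical"))
    stats::setNames(as.numeric(counts[classes]) / nrow(X), classes)
  else priors[classes]
  feat <- colnames(X)
  if (is.null(feat)) feat <- paste0("F", seq_len(d))
  new("MLHDModel", means = means, covInv = Sinv, priors = pr,
      classes = classes, features = feat, ridged = ridged)
}

#' Predict classes from an MLHD model
#' @param object an \linkS4class{MLHDModel}.
#' @param features numeric matrix with the model's features.
#' @return character predicted class labels.
#' @export
setMethod("predict", "MLHDModel", function(object, features) {
  X <- as.matrix(features)
  disc <- vapply(seq_along(object@classes), function(k) {
    mu <- object@means[k, ]
    as.vector(X %*% (object@covInv %*% mu)) -
      0.5 * as.numeric(crossprod(mu, object@covInv %*% mu)) +
      log(object@priors[k])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  object@classes[max.col(disc, ties.method = "first")]
})

# stratified k-fold CV accuracy of the MLHD on a feature subset
mlhdCvAccuracy <- function(X, labels, k = 5, folds = NULL, seed = 1,
                           priors = "equal") {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(folds)) folds <- withSeed(seed, makeFolds(n, k, strata = labels))
  pred <- character(n)
  for (f in unique(folds)) {
    tr <- folds != f
    model <- mlhdFit(X[tr, , drop = FALSE], labels[tr], priors = priors)
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  mean(pred == labels)
}

#' Split descriptors into pathway-linked and uncorrelated subsets
#'
#' The linked subset collects every descriptor appearing in any retained
#' passing model of a flagged pathway. The uncorrelated subset collects the
#' remaining descriptors whose absolute Pearson correlation with every linked
#' descriptor is below \code{corCutoff}; descriptors correlated with the
#' linked set belong to neither subset.
#'
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @param populations list of \linkS4class{ModelPopulation}.
#' @param corCutoff absolute correlation cutoff (default 0.5).
#' @return A \linkS4class{FeatureSplit}.
#' @export
splitFeatures <- function(descriptors, populations, corCutoff = 0.5) {
  linked <- character()
  for (popn in populations) {
    if (!isFlagged(popn)) next
    for (m in populationModels(popn))
      if (popPasses(popn, m))
        linked <- union(linked, m@triple)
  }
  if (length(linked) == 0L) stop("no PCF-linked models")
  v <- descriptorValues(descriptors)
  linked <- intersect(colnames(v), linked)
  rest <- setdiff(colnames(v), linked)
  if (length(rest)) {
    cm <- abs(stats::cor(v[, rest, drop = FALSE], v[, linked, drop = FALSE]))
    cm[is.na(cm)] <- 0          # constant columns cannot be correlated
    uncorrelated <- rest[apply(cm, 1, max) < corCutoff]
  } else uncorrelated <- character()
  new("FeatureSplit", linked = linked, uncorrelated = uncorrelated,
      corCutoff = corCutoff)
}

#' GA search for predictive feature subsets of a toxicity classifier
#'
#' Repeated GA runs over chromosomes of \code{chromosomeLen} feature indices
#' drawn from \code{subset}; fitness is the stratified k-fold cross-validated
#' accuracy of the MLHD classifier (fold assignment fixed per search).
#' Infeasible chromosomes receive fitness 0. Each run contributes its best
#' model to the returned population, so the accuracy distribution has one
#' value per run. The reported accuracy of a selected model is re-estimated
#' under a second, independent fold assignment (the selection fitness itself
#' is a maximum over many chromosomes and therefore optimistic); both values
#' are kept on the model.
#'
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @param labels named (by compound) or ordered class labels.
#' @param subset character descriptor ids to search within (>= 3).
#' @param chromosomeLen features per model (default 3).
#' @param kFolds CV folds (default 5).
#' @param nRuns independent GA runs (default 25).
#' @param population,generations,mutationRate GA hyper-parameters.
#' @param priors passed to \code{\link{mlhdFit}}.
#' @param seed integer seed.
#' @return list with \code{models} (list of list(features, accuracy)),
#'   \code{accuracies} (numeric, one per run) and \code{settings}.
#' @export
gaClassifierSearch <- function(descriptors, labels, subset, chromosomeLen = 3,
                               kFolds = 5, nRuns = 25, population = 20,
                               generations = 25, mutationRate = 1 / 3,
                               priors = "equal", seed = 1) {
  v <- descriptorValues(descriptors)
  if (!all(subset %in% colnames(v))) stop("unknown descriptors in subset")
  if (length(subset) < chromosomeLen)
    stop("subset must contain at least ", chromosomeLen, " features")
  X <- v[, subset, drop = FALSE]
  labels <- as.character(labels)
  nd <- ncol(X)
  withSeed(seed, {
    folds <- makeFolds(length(labels), kFolds, strata = labels)
    # a second, independent fold assignment re-estimates the accuracy of each
    # selected model: the maximum of cross-validated accuracies over the many
    # chromosomes a search visits is strongly optimistic, and decoupling
    # selection from reporting removes most of that winner's-curse bias
    foldsEval <- makeFolds(length(labels), kFolds, strata = labels)
    cache <- new.env(parent = emptyenv())
    fitness <- function(chrom) {
      key <- paste(sort(chrom), collapse = "-")
      if (!is.null(cache[[key]])) return(cache[[key]])
      val <- tryCatch(
        mlhdCvAccuracy(X[, chrom, drop = FALSE], labels, folds = folds,
                       priors = priors),
        error = function(e) 0)
      cache[[key]] <- val
      val
    }
    repair <- function(chrom) {
      while (anyDuplicated(chrom))
        chrom[duplicated(chrom)] <- sample.int(nd, sum(duplicated(chrom)))
      chrom
    }
    models <- vector("list", nRuns)
    for (run in seq_len(nRuns)) {
      pop <- replicate(population, sample.int(nd, chromosomeLen),
                       simplify = FALSE)
      fit <- vapply(pop, fitness, numeric(1))
      for (gen in seq_len(generations)) {
        elite <- pop[[which.max(fit)]]
        newPop <- vector("list", population)
        newPop[[1]] <- elite
        for (i in 2:population) {
          pick <- function() {
            cand <- sample.int(population, 2)
            pop[[cand[which.max(fit[cand])]]]
          }
          p1 <- pick(); p2 <- pick()
          child <- ifelse(stats::runif(chromosomeLen) < 0.5, p1, p2)
          mut <- stats::runif(chromosomeLen) < mutationRate
          if (any(mut)) child[mut] <- sample.int(nd, sum(mut), replace = TRUE)
          newPop[[i]] <- repair(child)
        }
        pop <- newPop
        fit <- vapply(pop, fitness, numeric(1))
      }
      b <- which.max(fit)
      acc <- tryCatch(
        mlhdCvAccuracy(X[, pop[[b]], drop = FALSE], labels, folds = foldsEval,
                       priors = priors),
        error = function(e) 0)
      models[[run]] <- list(features = subset[sort(pop[[b]])],
                            accuracy = acc, fitness = fit[b])
    }
    list(models = models,
         accuracies = vapply(models, `[[`, numeric(1), "accuracy"),
         settings = list(chromosomeLen = chromosomeLen, kFolds = kFolds,
                         nRuns = nRuns, population = population,
                         generations = generations,
                         mutationRate = mutationRate, priors = priors,
                         seed = as.integer(seed)))
  })
}

#' Compare the accuracy distributions of two feature subsets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the per-run model
#' accuracies of the two searches, with means and their difference.
#'
#' @param accLinked,accUncorrelated numeric accuracy vectors (>= 20 each).
#' @return list with \code{p.value}, \code{meanLinked}, \code{meanUncorrelated}
#'   and \code{difference}.
#' @export
compareSubsets <- function(accLinked, accUncorrelated) {
  if (length(accLinked) < 20 || length(accUncorrelated) < 20)
    stop("need at least 20 models per distribution")
  w <- suppressWarnings(stats::wilcox.test(accLinked, accUncorrelated,
                                           alternative = "two.sided"))
  list(p.value = w$p.value,
       meanLinked = mean(accLinked),
       meanUncorrelated = mean(accUncorrelated),
       difference = mean(accLinked) - mean(accUncorrelated))
}

#' Representative model from the most frequent features
#'
#' Takes the three features most frequently selected across the model
#' population (ties broken by the higher mean fitness of the models containing
#' the feature; fewer than three distinct features means all are used), refits
#' the MLHD, and reports stratified cross-validated sensitivity, specificity
#' and confusion counts (the \code{positive} class is "toxic" by default),
#' plus compound coordinates on the first principal components of the selected
#' features.
#'
#' @param searchResult result of \code{\link{gaClassifierSearch}}.
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @param labels class labels in compound order.
#' @param positive the positive class (default "toxic").
#' @param kFolds CV folds (default 5).
#' @param seed integer seed for the CV fold assignment.
#' @return list with \code{features}, \code{model} (\linkS4class{MLHDModel}),
#'   \code{cvAccuracy}, \code{sensitivity}, \code{specificity},
#'   \code{confusion} (tp, fn, fp, tn) and \code{pcaCoords}.
#' @export
representativeModel <- function(searchResult, descriptors, labels,
                                positive = "toxic", kFolds = 5, seed = 1) {
  models <- searchResult$models
  if (!length(models)) stop("empty model population")
  labels <- as.character(labels)
  feats <- unlist(lapply(models, `[[`, "features"))
  freq <- sort(table(feats), decreasing = TRUE)
  meanFit <- vapply(names(freq), function(f)
    mean(vapply(models, function(m)
      if (f %in% m$features) m$accuracy else NA_real_, numeric(1)),
      na.rm = TRUE), numeric(1))
  ord <- order(-as.numeric(freq), -meanFit)
  take <- min(3L, length(freq))
  chosen <- names(freq)[ord][seq_len(take)]
  v <- descriptorValues(descriptors)
  X <- v[, chosen, drop = FALSE]
  model <- mlhdFit(X, labels, priors = searchResult$settings$priors)
  folds <- withSeed(seed, makeFolds(length(labels), kFolds, strata = labels))
  pred <- character(length(labels))
  for (f in unique(folds)) {
    tr <- folds != f
    m <- mlhdFit(X[tr, , drop = FALSE], labels[tr],
                 priors = searchResult$settings$priors)
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  isPos <- labels == positive
  tp <- sum(pred == positive & isPos); fn <- sum(pred != positive & isPos)
  fp <- sum(pred == positive & !isPos); tn <- sum(pred != positive & !isPos)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nPc <- min(3L, ncol(pc$x))
  list(features = chosen, model = model,
       cvAccuracy = mean(pred == labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
       pcaCoords = pc$x[, seq_len(nPc), drop = FALSE])
}
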