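# Three-descriptor interaction regressions linking physico-chemical
# descriptors to a pathway activity component, with genetic-algorithm model
# search under cross-validated fitness.

# does a model pass the selection rule of its population? fitness threshold
# on the training CV R2, plus external validation on the held-out test split
# (a model whose test R2 is negative does not generalize and is rejected)
modelPasses <- function(m, threshold, testR2Min = 0) {
  if (!is.finite(m@cvR2) || m@cvR2 < threshold) return(FALSE)
  if (is.na(m@testR2)) return(TRUE)
  m@testR2 >= testR2Min
}

popPasses <- function(popn, m) {
  tmin <- popn@settings$testR2Min
  if (is.null(tmin)) tmin <- 0
  modelPasses(m, popn@settings$threshold, tmin)
}

eq1Design <- function(D) {
  D <- as.matrix(D)
  cbind(1, D[, 1], D[, 2], D[, 3],
        D[, 1] * D[, 2], D[, 1] * D[, 3], D[, 2] * D[, 3])
}

.descCols <- function(descriptors, triple) {
  v <- if (is(descriptors, "DescriptorMatrix")) descriptorValues(descriptors)
       else as.matrix(descriptors)
  v[, triple, drop = FALSE]
}

# least-squares core; returns NULL on rank deficiency
eq1Solve <- function(y, D) {
  X <- eq1Design(D)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  beta <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% beta)
  list(beta = beta, fitted = fitted, rss = sum((y - fitted)^2))
}

#' Per-compound pathway activity targets
#'
#' The regression target for a pathway is, per compound, the mean of its
#' treated replicate scores on the chosen principal component (the second PC
#' by default, which carries the toxicity-linked signal).
#'
#' @param indexSet a \linkS4class{PathwayIndexSet}.
#' @param study the \linkS4class{ExpressionStudy}.
#' @param whichPc which retained PC to target (default 2). Pathways for which
#'   this PC was not retained are dropped and listed in the \code{"dropped"}
#'   attribute.
#' @return numeric compounds x pathways matrix of targets.
#' @export
pathwayTargets <- function(indexSet, study, whichPc = 2) {
  cd <- sampleMeta(study)
  drugs <- compoundIds(study)
  keep <- retainedPathways(indexSet)[vapply(retainedPathways(indexSet),
    function(p) ncol(indexSet@scores[[p]]) >= whichPc, logical(1))]
  dropped <- setdiff(retainedPathways(indexSet), keep)
  out <- matrix(NA_real_, length(drugs), length(keep),
                dimnames = list(drugs, keep))
  for (drug in drugs) {
    idx <- rownames(cd)[cd$compound_id == drug & cd$role == "treated"]
    if (length(idx) == 0L) stop("compound without treated samples: ", drug)
    for (pw in keep)
      out[drug, pw] <- mean(indexSet@scores[[pw]][idx, whichPc])
  }
  attr(out, "dropped") <- dropped
  out
}

#' Fit the three-descriptor interaction regression
#'
#' Ordinary least squares of
#' \deqn{y = a + b D_1 + c D_2 + d D_3 + e D_1 D_2 + f D_1 D_3 + g D_2 D_3 + \epsilon.}
#' A rank-deficient design is an error ("collinear triple"). A constant target
#' is a degenerate case: the slope coefficients are zero and the training R2
#' is defined as 0 (keeping GA fitness totally ordered).
#'
#' @param y numeric compound-level target vector.
#' @param descriptors a \linkS4class{DescriptorMatrix} or numeric matrix.
#' @param triple three distinct descriptor ids (or column indices).
#' @param pathwayId,pcIndex optional bookkeeping fields.
#' @return An \linkS4class{Eq1Model} (cvR2 and testR2 are NA here).
#' @export
fitEq1 <- function(y, descriptors, triple, pathwayId = NA_character_,
                   pcIndex = 2L) {
  if (length(triple) != 3L || anyDuplicated(triple))
    stop("triple must name three distinct descriptors")
  D <- .descCols(descriptors, triple)
  if (length(y) < 8) stop("need at least 8 compounds to fit 7 parameters")
  tripleIds <- if (is.character(triple)) triple else colnames(D)
  if (is.null(tripleIds)) tripleIds <- paste0("D", triple)
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-24) {
    beta <- c(mean(y), rep(0, 6))
    return(new("Eq1Model", pathwayId = pathwayId, pcIndex = as.integer(pcIndex),
               triple = tripleIds,
               coefficients = stats::setNames(beta, letters[1:7]),
               trainR2 = 0, cvR2 = NA_real_, testR2 = NA_real_, sigma2 = 0))
  }
  fit <- eq1Solve(y, D)
  if (is.null(fit)) stop("collinear triple")
  n <- length(y)
  new("Eq1Model", pathwayId = pathwayId, pcIndex = as.integer(pcIndex),
      triple = tripleIds,
      coefficients = stats::setNames(as.numeric(fit$beta), letters[1:7]),
      trainR2 = 1 - fit$rss / tss, cvR2 = NA_real_, testR2 = NA_real_,
      sigma2 = fit$rss / max(n - 7, 1))
}

#' Predict from a fitted Eq1 model
#' @param object an \linkS4class{Eq1Model}.
#' @param descriptors a \linkS4class{DescriptorMatrix} or numeric matrix
#'   containing the model's triple.
#' @return numeric predictions.
#' @export
setMethod("predict", "Eq1Model", function(object, descriptors) {
  D <- .descCols(descriptors, object@triple)
  as.vector(eq1Design(D) %*% object@coefficients)
})

#' Cross-validated R2 of a descriptor triple
#'
#' k-fold cross-validation: out-of-fold predictions are pooled and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} is computed once on the pooled vector
#' (it may be negative). Fold assignment is drawn deterministically from
#' \code{seed}.
#'
#' @param y numeric target vector.
#' @param descriptors a \linkS4class{DescriptorMatrix} or numeric matrix.
#' @param triple three distinct descriptor ids or indices.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param folds optional explicit fold assignment (overrides \code{seed}).
#' @return numeric cross-validated R2.
#' @export
cvR2 <- function(y, descriptors, triple, k = 5, seed = 1, folds = NULL) {
  n <- length(y)
  if (n < k) stop("need at least k compounds")
  D <- .descCols(descriptors, triple)
  if (nrow(D) != n) stop("y and descriptors disagree on the number of compounds")
  if (is.null(folds)) folds <- withSeed(seed, makeFolds(n, k))
  pred <- numeric(n)
  for (f in unique(folds)) {
    tr <- folds != f
    if (sum(tr) < 8) stop("fold with fewer than 8 training compounds")
    fit <- eq1Solve(y[tr], D[tr, , drop = FALSE])
    if (is.null(fit)) stop("collinear triple")
    pred[!tr] <- as.vector(eq1Design(D[!tr, , drop = FALSE]) %*% fit$beta)
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-24) return(0)
  1 - sum((y - pred)^2) / tss
}

#' Genetic-algorithm search for predictive descriptor triples
#'
#' Compounds are first split into a training fraction (\code{split}, default
#' 2/3) and a held-out test fraction. Repeated GA runs search chromosomes of
#' three descriptor indices on the training split; fitness is the k-fold
#' cross-validated R2 within training (fold assignment fixed per search so
#' fitness values are comparable and cacheable). Each run uses tournament
#' selection (size 2), uniform crossover, per-gene point mutation and elitism,
#' with optional early stop once the best fitness reaches \code{goalFitness}.
#' Infeasible chromosomes (collinear triples) receive fitness -Inf.
#'
#' The model population collects the best model of every run, deduplicated
#' keeping the best-fitness instance. Retained models are refit on the full
#' training split and their R2 on the untouched test split is recorded. A
#' model passes selection when its fitness reaches \code{threshold} and it
#' validates externally (test-split R2 >= \code{testR2Min}; default 0, i.e.
#' the model must generalize at all) -- with small compound panels a
#' best-of-thousands cross-validated R2 alone is anti-conservative, and the
#' held-out split is what rejects chance models. Any passing model marks the
#' pathway as PCF-linked.
#'
#' @param y numeric compound-level target vector.
#' @param descriptors a \linkS4class{DescriptorMatrix} or numeric matrix
#'   (>= 4 descriptors; >= 12 compounds).
#' @param nRuns independent GA runs (each contributes one model).
#' @param population,generations,mutationRate GA hyper-parameters.
#' @param threshold cross-validated R2 a model must reach for the pathway to be
#'   flagged (default 0.5).
#' @param testR2Min minimum test-split R2 for a threshold-passing model to
#'   count as validated (default 0).
#' @param cvFolds folds for the fitness cross-validation (default 5).
#' @param split training fraction (default 2/3).
#' @param goalFitness early-stop fitness (default Inf: no early stop).
#' @param seed integer seed.
#' @param pathwayId,pcIndex bookkeeping fields stored on the models.
#' @return A \linkS4class{ModelPopulation}.
#' @export
gaSearch <- function(y, descriptors, nRuns = 10, population = 30,
                     generations = 60, mutationRate = 1 / 3, threshold = 0.5,
                     testR2Min = 0, cvFolds = 5, split = 2 / 3,
                     goalFitness = Inf, seed = 1,
                     pathwayId = NA_character_, pcIndex = 2L) {
  D <- if (is(descriptors, "DescriptorMatrix")) descriptorValues(descriptors)
       else as.matrix(descriptors)
  nd <- ncol(D)
  n <- length(y)
  if (n < 12) stop("need at least 12 compounds")
  if (nd < 4) stop("need at least 4 descriptors")
  ids <- colnames(D)
  if (is.null(ids)) ids <- paste0("D", seq_len(nd))
  withSeed(seed, {
    trainIdx <- sort(sample.int(n, round(split * n)))
    testIdx <- setdiff(seq_len(n), trainIdx)
    yTr <- y[trainIdx]
    DTr <- D[trainIdx, , drop = FALSE]
    folds <- makeFolds(length(yTr), cvFolds)
    tssTr <- sum((yTr - mean(yTr))^2)
    cache <- new.env(parent = emptyenv())
    fitness <- function(chrom) {
      key <- paste(sort(chrom), collapse = "-")
      if (!is.null(cache[[key]])) return(cache[[key]])
      val <- tryCatch({
        if (tssTr < 1e-24) 0
        else {
          pred <- numeric(length(yTr))
          ok <- TRUE
          for (f in seq_len(cvFolds)) {
            tr <- folds != f
            fit <- eq1Solve(yTr[tr], DTr[tr, chrom, drop = FALSE])
            if (is.null(fit)) { ok <- FALSE; break }
            pred[!tr] <- as.vector(
              eq1Design(DTr[!tr, chrom, drop = FALSE]) %*% fit$beta)
          }
          if (ok) 1 - sum((yTr - pred)^2) / tssTr else -Inf
        }
      }, error = function(e) -Inf)
      cache[[key]] <- val
      val
    }
    randomChrom <- function() sample.int(nd, 3)
    repair <- function(chrom) {
      while (anyDuplicated(chrom))
        chrom[duplicated(chrom)] <- sample.int(nd, sum(duplicated(chrom)))
      chrom
    }
    runBest <- vector("list", nRuns)
    for (run in seq_len(nRuns)) {
      pop <- replicate(population, randomChrom(), simplify = FALSE)
      fit <- vapply(pop, fitness, numeric(1))
      for (gen in seq_len(generations)) {
        if (max(fit) >= goalFitness) break
        elite <- pop[[which.max(fit)]]
        newPop <- vector("list", population)
        newPop[[1]] <- elite
        for (i in 2:population) {
          pick <- function() {
            cand <- sample.int(population, 2)
            pop[[cand[which.max(fit[cand])]]]
          }
          p1 <- pick(); p2 <- pick()
          child <- ifelse(stats::runif(3) < 0.5, p1, p2)
          mut <- stats::runif(3) < mutationRate
          if (any(mut)) child[mut] <- sample.int(nd, sum(mut), replace = TRUE)
          newPop[[i]] <- repair(child)
        }
        pop <- newPop
        fit <- vapply(pop, fitness, numeric(1))
      }
      b <- which.max(fit)
      runBest[[run]] <- list(chrom = sort(pop[[b]]), fitness = fit[b])
    }
    # deduplicate run bests, keeping the best-fitness instance
    keys <- vapply(runBest, function(r) paste(r$chrom, collapse = "-"),
                   character(1))
    ord <- order(vapply(runBest, function(r) -r$fitness, numeric(1)))
    seen <- character()
    models <- list()
    for (i in ord) {
      if (keys[i] %in% seen) next
      seen <- c(seen, keys[i])
      chrom <- runBest[[i]]$chrom
      m <- tryCatch(fitEq1(yTr, DTr, chrom, pathwayId = pathwayId,
                           pcIndex = pcIndex), error = function(e) NULL)
      if (is.null(m)) next
      m@triple <- ids[chrom]
      m@cvR2 <- runBest[[i]]$fitness
      if (length(testIdx) >= 2) {
        predTest <- as.vector(
          eq1Design(D[testIdx, chrom, drop = FALSE]) %*% m@coefficients)
        tssTest <- sum((y[testIdx] - mean(y[testIdx]))^2)
        m@testR2 <- if (tssTest > 1e-24)
          1 - sum((y[testIdx] - predTest)^2) / tssTest else NA_real_
      }
      models <- c(models, m)
    }
    pass <- vapply(models, modelPasses, logical(1),
                   threshold = threshold, testR2Min = testR2Min)
    flagged <- any(pass)
    kept <- if (flagged) models[pass] else models[seq_len(min(1, length(models)))]
    new("ModelPopulation", pathwayId = pathwayId, models = kept,
        settings = list(nRuns = nRuns, population = population,
                        generations = generations,
                        mutationRate = mutationRate, threshold = threshold,
                        testR2Min = testR2Min, cvFolds = cvFolds,
                        split = split, goalFitness = goalFitness,
                        trainIdx = trainIdx, testIdx = testIdx,
                        folds = folds),
        seed = as.integer(seed), flagged = flagged)
  })
}

#' Fraction of explained sum-of-squares attributable to interaction terms
#'
#' The full Eq1 model and a main-effects-only refit (intercept + three linear
#' terms) are both fit to the supplied data; the share is
#' \eqn{(SS_{expl}(full) - SS_{expl}(main)) / SS_{expl}(full)}, clipped to
#' [0, 1]. NA when the full model explains nothing.
#'
#' @param model an \linkS4class{Eq1Model}.
#' @param y numeric target vector.
#' @param descriptors a \linkS4class{DescriptorMatrix} or numeric matrix.
#' @return numeric share in [0, 1], or NA.
#' @export
interactionShare <- function(model, y, descriptors) {
  D <- .descCols(descriptors, model@triple)
  tss <- sum((y - mean(y))^2)
  full <- eq1Solve(y, D)
  if (is.null(full)) stop("collinear triple")
  ssFull <- tss - full$rss
  if (ssFull <= 1e-24) return(NA_real_)
  Xm <- cbind(1, D)
  qrm <- qr(Xm)
  rssMain <- sum(qr.resid(qrm, y)^2)
  ssMain <- tss - rssMain
  min(max((ssFull - ssMain) / ssFull, 0), 1)
}

#' Descriptor-group interaction network
#'
#' Summarizes model populations as a weighted graph over descriptor groups:
#' one node per group, and the weight of edge (g1, g2) counts the pathways
#' having at least one retained passing model whose triple pairs a g1 with a
#' g2 descriptor in an interaction term (the three pairwise products of a
#' triple). Self-edges are allowed.
#'
#' @param populations list of \linkS4class{ModelPopulation}.
#' @param descriptors the \linkS4class{DescriptorMatrix} (for group labels).
#' @return list with \code{graph} (an \pkg{igraph} weighted graph) and
#'   \code{edges} (data.frame group1, group2, weight).
#' @export
descriptorGroupNetwork <- function(populations, descriptors) {
  groups <- descriptorGroups(descriptors)
  pairCount <- list()
  for (popn in populations) {
    if (!isFlagged(popn)) next
    pwPairs <- character()
    for (m in populationModels(popn)) {
      if (!popPasses(popn, m)) next
      g <- unname(groups[m@triple])
      prs <- list(sort(g[c(1, 2)]), sort(g[c(1, 3)]), sort(g[c(2, 3)]))
      pwPairs <- union(pwPairs, vapply(prs, paste, character(1), collapse = "||"))
    }
    for (pr in pwPairs)
      pairCount[[pr]] <- (if (is.null(pairCount[[pr]])) 0 else pairCount[[pr]]) + 1
  }
  if (length(pairCount) == 0L) {
    edges <- data.frame(group1 = character(), group2 = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                edges = edges))
  }
  parts <- strsplit(names(pairCount), "||", fixed = TRUE)
  edges <- data.frame(group1 = vapply(parts, `[`, character(1), 1),
                      group2 = vapply(parts, `[`, character(1), 2),
                      weight = unlist(pairCount, use.names = FALSE),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$group1, edges$group2), ]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  list(graph = g, edges = edges)
}

#' Tabular summary of QSPR model populations
#'
#' One row per flagged pathway: the average cross-validated R2 over its
#' retained model population, the best test-split R2, and the descriptor
#' groups of the best model's triple.
#'
#' @param populations list of \linkS4class{ModelPopulation}.
#' @param descriptors the \linkS4class{DescriptorMatrix}.
#' @return data.frame.
#' @export
qsprSummary <- function(populations, descriptors) {
  groups <- descriptorGroups(descriptors)
  rows <- lapply(populations, function(popn) {
    if (!isFlagged(popn)) return(NULL)
    ms <- populationModels(popn)
    cv <- vapply(ms, function(m) m@cvR2, numeric(1))
    te <- vapply(ms, function(m) m@testR2, numeric(1))
    best <- ms[[1]]
    data.frame(pathway = popn@pathwayId,
               n_models = length(ms),
               r2_cv_average = mean(cv, na.rm = TRUE),
               r2_test_best = if (all(is.na(te))) NA_real_ else max(te, na.rm = TRUE),
               group1 = unname(groups[best@triple[1]]),
               group2 = unname(groups[best@triple[2]]),
               group3 = unname(groups[best@triple[3]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), n_models = integer(),
                      r2_cv_average = numeric(), r2_test_best = numeric(),
                      group1 = character(), group2 = character(),
                      group3 = character(), stringsAsFactors = FALSE)
  out
}

modelToList <- function(m) {
  list(pathway = m@pathwayId, pc = m@pcIndex, triple = m@triple,
       coefficients = as.list(m@coefficients), train_r2 = m@trainR2,
       cv_r2 = m@cvR2, test_r2 = m@testR2, sigma2 = m@sigma2)
}

#' Write model populations to JSON
#'
#' @param populations list of \linkS4class{ModelPopulation}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeModelPopulations <- function(populations, path) {
  out <- lapply(populations, function(popn)
    list(pathway = popn@pathwayId, flagged = popn@flagged, seed = popn@seed,
         settings = popn@settings[setdiff(names(popn@settings),
                                          c("trainIdx", "testIdx"))],
         models = lapply(populationModels(popn), modelToList)))
  names(out) <- vapply(populations, function(p) p@pathwayId, character(1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
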