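# Hotelling T2 statistics on pathway activity indices: per-drug perturbation
# versus matched controls, toxic-versus-nontoxic differential modulation, and
# hierarchical clustering of drug perturbation profiles.

#' Two-sample Hotelling T2 statistic
#'
#' For groups A (n x p) and B (m x p),
#' \deqn{T^2 = \frac{nm}{n+m} d' S^{-1} d}
#' with d the difference of group means and S the pooled covariance, and
#' \deqn{F = T^2 \frac{n+m-p-1}{p (n+m-2)}}
#' which follows an F(p, n+m-p-1) distribution under the null of equal means;
#' the p-value is the upper F tail. A singular pooled covariance is
#' ridge-regularized with \eqn{\lambda = 10^{-8} \, tr(S)/p} and the result is
#' flagged; too few samples (n+m-2 < p) is an error.
#'
#' @param groupA,groupB numeric matrices (or vectors when p = 1) with
#'   observations in rows.
#' @return list with \code{T2}, \code{F}, \code{p.value}, \code{df} (numerator,
#'   denominator) and \code{ridged}.
#' @export
hotellingT2 <- function(groupA, groupB) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (ncol(A) != ncol(B)) stop("groups must share the same dimension")
  n <- nrow(A); m <- nrow(B); p <- ncol(A)
  if (n + m - 2 < p) stop("insufficient samples for a ", p, "-dimensional test")
  d <- colMeans(A) - colMeans(B)
  Sa <- if (n > 1) stats::cov(A) else matrix(0, p, p)
  Sb <- if (m > 1) stats::cov(B) else matrix(0, p, p)
  S <- ((n - 1) * Sa + (m - 1) * Sb) / (n + m - 2)
  ridged <- FALSE
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(S) < 1e-12) {
    lambda <- 1e-8 * sum(diag(S)) / p
    if (lambda <= 0) lambda <- 1e-8
    Sinv <- solve(S + diag(lambda, p))
    ridged <- TRUE
  }
  T2 <- as.numeric((n * m / (n + m)) * crossprod(d, Sinv %*% d))
  T2 <- max(T2, 0)
  Fstat <- T2 * (n + m - p - 1) / (p * (n + m - 2))
  pval <- stats::pf(Fstat, p, n + m - p - 1, lower.tail = FALSE)
  list(T2 = T2, F = Fstat, p.value = pval, df = c(p, n + m - p - 1),
       ridged = ridged)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated front-end to \code{\link[stats]{p.adjust}(method = "BH")}:
#' q-values are capped at 1 and monotone in p-value rank order.
#'
#' @param pValues numeric vector in [0, 1].
#' @return adjusted q-values in the input order.
#' @export
bhAdjust <- function(pValues) {
  if (anyNA(pValues) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Drug perturbation indices: T2 of treated versus matched controls
#'
#' For every treated compound and every retained pathway, the Hotelling T2
#' statistic compares the compound's treated sample scores with its matched
#' control group's scores on the retained PCs. Per-cell failures (e.g. too few
#' samples) are logged and yield NA rather than aborting the matrix.
#'
#' @param indexSet a \linkS4class{PathwayIndexSet}.
#' @param study the \linkS4class{ExpressionStudy} the scores came from.
#' @return A \linkS4class{PerturbationMatrix}.
#' @export
perturbationIndex <- function(indexSet, study) {
  cd <- sampleMeta(study)
  drugs <- compoundIds(study)
  pws <- retainedPathways(indexSet)
  t2 <- matrix(NA_real_, length(drugs), length(pws),
               dimnames = list(drugs, pws))
  issues <- data.frame(drug = character(), pathway = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (drug in drugs) {
    trIdx <- rownames(cd)[cd$compound_id == drug & cd$role == "treated"]
    mg <- unique(cd$match_group[cd$compound_id == drug & cd$role == "treated"])
    ctIdx <- rownames(cd)[cd$match_group %in% mg & cd$role == "control"]
    if (length(ctIdx) < 2)
      stop("compound ", drug, " lacks a matched control group of >= 2 samples")
    for (pw in pws) {
      sc <- indexSet@scores[[pw]]
      res <- tryCatch(hotellingT2(sc[trIdx, , drop = FALSE],
                                  sc[ctIdx, , drop = FALSE]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        issues <- rbind(issues, data.frame(drug = drug, pathway = pw,
                                           message = conditionMessage(res),
                                           stringsAsFactors = FALSE))
      } else t2[drug, pw] <- res$T2
    }
  }
  new("PerturbationMatrix", t2 = t2, issues = issues,
      params = list(maxPcs = indexSet@params$maxPcs))
}

#' Hierarchically cluster drugs by their perturbation profiles
#'
#' The default distance is 1 - Pearson correlation between drug rows of the
#' perturbation matrix (profile shape), with average linkage. Pathways with
#' any unavailable cell are dropped before clustering. If any drug profile is
#' constant, correlation is undefined and the computation falls back to
#' Euclidean distance with a warning.
#'
#' @param perturbation a \linkS4class{PerturbationMatrix}.
#' @param distance "correlation" (default) or "euclidean".
#' @param linkage linkage method for \code{\link[stats]{hclust}}.
#' @return list with \code{hclust} (the dendrogram), \code{order} (leaf order)
#'   and \code{distance} (the metric actually used).
#' @export
clusterDrugs <- function(perturbation, distance = "correlation",
                         linkage = "average") {
  v <- perturbationValues(perturbation)
  v <- v[, colSums(is.na(v)) == 0L, drop = FALSE]
  if (nrow(v) < 3) stop("need at least 3 drugs to cluster")
  if (ncol(v) == 0L) stop("no complete pathway columns to cluster on")
  used <- distance
  if (distance == "correlation") {
    if (any(apply(v, 1, stats::sd) < 1e-12)) {
      warning("constant drug profile: correlation undefined, using Euclidean distance")
      used <- "euclidean"
    }
  }
  d <- if (used == "correlation") stats::as.dist(1 - stats::cor(t(v)))
       else stats::dist(v)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = hc$labels[hc$order], distance = used)
}

#' Differentially modulated pathways between toxic and non-toxic exposure
#'
#' For each retained pathway, the Hotelling T2 statistic compares the retained
#' PC scores of toxic versus non-toxic exposures (control samples do not enter
#' the test). The unit of analysis is the compound: each compound's treated
#' replicate scores are averaged first, so replicates are not treated as
#' independent exposures -- pooling raw replicates is anti-conservative when
#' pathway activity varies at the compound level (pseudoreplication), and the
#' compound-level test is what keeps the false discovery rate at its nominal
#' level. P-values are Benjamini-Hochberg adjusted across pathways and
#' pathways with q-value below \code{fdrLevel} are selected. Per-PC
#' pooled-variance t statistics decompose the multivariate signal.
#'
#' @param indexSet a \linkS4class{PathwayIndexSet}.
#' @param study the \linkS4class{ExpressionStudy}.
#' @param fdrLevel FDR level for selection (default 0.01).
#' @return A \linkS4class{DifferentialResult}.
#' @export
differentialPathways <- function(indexSet, study, fdrLevel = 0.01) {
  cd <- sampleMeta(study)
  labels <- toxicityLabels(study)
  toxIdx <- names(labels)[labels == "toxic"]
  nonIdx <- names(labels)[labels == "nontoxic"]
  if (length(toxIdx) == 0L || length(nonIdx) == 0L)
    stop("both toxicity classes must contain treated compounds")
  treatedOf <- split(rownames(cd)[cd$role == "treated"],
                     cd$compound_id[cd$role == "treated"])
  pws <- retainedPathways(indexSet)
  pooledT <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                 (nx + ny - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
  }
  rows <- lapply(pws, function(pw) {
    sc <- indexSet@scores[[pw]]
    agg <- do.call(rbind, lapply(treatedOf, function(ids)
      colMeans(sc[ids, , drop = FALSE])))
    A <- agg[toxIdx, , drop = FALSE]
    B <- agg[nonIdx, , drop = FALSE]
    if (nrow(A) < ncol(A) + 2 || nrow(B) < ncol(B) + 2)
      stop("toxicity classes too small for a ", ncol(A), "-PC test")
    h <- hotellingT2(A, B)
    data.frame(pathway = pw, n_genes = unname(indexSet@nGenes[pw]),
               T2 = h$T2, F = h$F, df1 = h$df[1], df2 = h$df[2],
               p_value = h$p.value,
               t_pc1 = pooledT(A[, 1], B[, 1]),
               t_pc2 = if (ncol(A) >= 2) pooledT(A[, 2], B[, 2]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- bhAdjust(tab$p_value)
  tab$selected <- tab$q_value < fdrLevel
  tab <- tab[, c("pathway", "n_genes", "T2", "F", "df1", "df2", "p_value",
                 "q_value", "selected", "t_pc1", "t_pc2")]
  new("DifferentialResult", table = tab, fdrLevel = fdrLevel)
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
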