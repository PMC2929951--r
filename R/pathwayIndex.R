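# Pathway activity indices: per-pathway PCA of the expression submatrix.

#' Compute per-pathway principal-component activity indices
#'
#' For every gene set with more than \code{minGenes - 1} member genes present
#' in the expression matrix (strictly more than 5 under the default), the
#' samples x genes submatrix is mean-centered per gene (optionally unit-scaled)
#' and decomposed with \code{\link[stats]{prcomp}}. The smallest number of
#' leading components whose cumulative variance fraction reaches
#' \code{varianceTarget} is retained, capped at \code{maxPcs}; the cap is
#' enforced dataset-wide even when it falls short of the target for a specific
#' pathway (such pathways are listed in \code{belowTarget} and a warning is
#' emitted). The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making downstream regression
#' targets reproducible.
#'
#' Pathways with too few matched genes, or with a zero-variance (degenerate)
#' submatrix, are excluded with a recorded reason rather than raising an error.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param minGenes minimum matched gene count for a pathway to be processed
#'   (default 6, i.e. strictly more than 5 genes).
#' @param varianceTarget cumulative variance fraction to reach (default 0.8).
#' @param maxPcs maximum retained components (default 2).
#' @param scale unit-scale genes before PCA? Default \code{FALSE}: genes are
#'   centered only, preserving amplitude information.
#' @return A \linkS4class{PathwayIndexSet}.
#' @export
computePathwayIndices <- function(study, geneSets, minGenes = 6,
                                  varianceTarget = 0.8, maxPcs = 2,
                                  scale = FALSE) {
  m <- exprsMatrix(study)
  sets <- geneSets(geneSets)
  scores <- list(); loadings <- list(); varFrac <- list()
  cumVar <- numeric(); nGenes <- integer(); belowTarget <- character()
  excluded <- data.frame(pathway = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (pw in names(sets)) {
    genes <- intersect(sets[[pw]], rownames(m))
    if (length(genes) < minGenes) {
      excluded <- rbind(excluded,
                        data.frame(pathway = pw, reason = "too few genes",
                                   stringsAsFactors = FALSE))
      next
    }
    sub <- t(m[genes, , drop = FALSE])          # samples x genes
    sds <- apply(sub, 2, stats::sd)
    if (all(sds < 1e-12) || (scale && any(sds < 1e-12))) {
      excluded <- rbind(excluded,
                        data.frame(pathway = pw, reason = "degenerate",
                                   stringsAsFactors = FALSE))
      next
    }
    pc <- stats::prcomp(sub, center = TRUE, scale. = scale)
    v <- pc$sdev^2
    tot <- sum(v)
    if (tot < 1e-24) {
      excluded <- rbind(excluded,
                        data.frame(pathway = pw, reason = "degenerate",
                                   stringsAsFactors = FALSE))
      next
    }
    frac <- v / tot
    nAvail <- sum(v > tot * 1e-12)
    mKeep <- which(cumsum(frac) >= varianceTarget - 1e-12)[1]
    if (is.na(mKeep)) mKeep <- nAvail
    mKeep <- min(mKeep, maxPcs, nAvail)
    if (cumsum(frac)[mKeep] < varianceTarget - 1e-12)
      belowTarget <- c(belowTarget, pw)
    rot <- pc$rotation[, seq_len(mKeep), drop = FALSE]
    sc <- pc$x[, seq_len(mKeep), drop = FALSE]
    for (j in seq_len(mKeep)) {                  # sign convention
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
    }
    colnames(rot) <- colnames(sc) <- paste0("PC", seq_len(mKeep))
    scores[[pw]] <- sc
    loadings[[pw]] <- rot
    varFrac[[pw]] <- frac[seq_len(mKeep)]
    cumVar[[pw]] <- sum(frac[seq_len(mKeep)])
    nGenes[[pw]] <- length(genes)
  }
  if (length(belowTarget))
    warning(length(belowTarget), " pathway(s) fall short of the variance ",
            "target with ", maxPcs, " components")
  new("PathwayIndexSet", scores = scores, loadings = loadings,
      varFrac = varFrac, cumVar = cumVar, nGenes = nGenes,
      excluded = excluded, belowTarget = belowTarget,
      params = list(minGenes = minGenes, varianceTarget = varianceTarget,
                    maxPcs = maxPcs, scaled = scale),
      sampleIds = colnames(m))
}

#' Per-pathway variance-explained report
#'
#' @param indexSet a \linkS4class{PathwayIndexSet}.
#' @return data.frame with one row per retained pathway: pathway, n_genes,
#'   pc1_fraction, pc2_fraction (NA when only one PC is retained) and the
#'   cumulative retained fraction.
#' @export
varianceReport <- function(indexSet) {
  pws <- retainedPathways(indexSet)
  if (length(pws) == 0L) stop("empty index set")
  data.frame(
    pathway = pws,
    n_genes = unname(indexSet@nGenes[pws]),
    pc1_fraction = vapply(pws, function(p) indexSet@varFrac[[p]][1], numeric(1)),
    pc2_fraction = vapply(pws, function(p) {
      v <- indexSet@varFrac[[p]]
      if (length(v) >= 2) v[2] else NA_real_
    }, numeric(1)),
    cumulative = unname(indexSet@cumVar[pws]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write pathway scores, loadings and the exclusion log as TSV
#'
#' Scores and loadings are emitted as long-format tables (pathway, id, PC,
#' value); exclusions as (pathway, reason).
#'
#' @param indexSet a \linkS4class{PathwayIndexSet}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writePathwayIndices <- function(indexSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(lst, idName) {
    do.call(rbind, lapply(names(lst), function(pw) {
      m <- lst[[pw]]
      data.frame(pathway = pw,
                 id = rep(rownames(m), ncol(m)),
                 pc = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m), stringsAsFactors = FALSE)
    }))
  }
  writeTsv(long(indexSet@scores, "sample"), file.path(dir, "pathway_scores.tsv"))
  writeTsv(long(indexSet@loadings, "gene"), file.path(dir, "pathway_loadings.tsv"))
  writeTsv(varianceReport(indexSet), file.path(dir, "variance_report.tsv"))
  writeTsv(indexSet@excluded, file.path(dir, "excluded_pathways.tsv"))
  invisible(dir)
}
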