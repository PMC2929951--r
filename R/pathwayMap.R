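# Jaccard-overlap pathway map: similarity matrix, average-linkage clustering
# with cophenetic verification, and a permutation test of map proximity
# between two pathway label sets.

#' Jaccard similarity matrix between gene sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}: the number of genes shared by two
#' pathways divided by the number of distinct genes in their union. Computed
#' via an incidence-matrix cross product. Sets may optionally be restricted to
#' the genes present in the expression data first; sets left empty by the
#' restriction are excluded with a warning.
#'
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param restrictToGenes optional character vector of gene ids to intersect
#'   every set with.
#' @return A \linkS4class{PathwaySimilarity}.
#' @export
jaccardMatrix <- function(geneSets, restrictToGenes = NULL) {
  sets <- geneSets(geneSets)
  if (!is.null(restrictToGenes))
    sets <- lapply(sets, intersect, restrictToGenes)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) empty after restriction, excluded: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) < 2) stop("need at least 2 non-empty sets")
  universe <- unique(unlist(sets, use.names = FALSE))
  inc <- matrix(0L, length(sets), length(universe),
                dimnames = list(names(sets), universe))
  for (i in seq_along(sets)) inc[i, match(sets[[i]], universe)] <- 1L
  inter <- tcrossprod(inc)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, `+`) - inter
  sim <- inter / uni
  diag(sim) <- 1
  new("PathwaySimilarity", sim = sim)
}

#' Cluster pathways on Jaccard distance and verify with cophenetic correlation
#'
#' Hierarchical clustering (average linkage by default) on distance
#' \eqn{1 - J}. The faithfulness of the dendrogram is verified by the
#' cophenetic correlation between tree-implied and input distances; NA when
#' the input distances are constant.
#'
#' @param similarity a \linkS4class{PathwaySimilarity}.
#' @param linkage linkage method (default "average").
#' @return list with \code{hclust} and \code{copheneticR}.
#' @export
clusterPathways <- function(similarity, linkage = "average") {
  sim <- similarityValues(similarity)
  if (nrow(sim) < 3) stop("need at least 3 pathways to cluster")
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = linkage)
  cph <- stats::cophenetic(hc)
  r <- if (stats::sd(d) < 1e-12 || stats::sd(cph) < 1e-12) NA_real_
       else stats::cor(d, cph)
  list(hclust = hc, copheneticR = r)
}

#' Permutation test of proximity between two pathway sets on the map
#'
#' The observed statistic is the mean cophenetic (tree) distance over all
#' (pcfLinked x toxLinked) pathway pairs; small values mean the two sets sit
#' close together on the pathway map. The null redraws both label sets as
#' uniform leaf subsets of the same sizes \code{nPerm} times, and
#' \eqn{p = (1 + \#\{null \le observed\}) / (nPerm + 1)} (resolution
#' 1/(nPerm+1)). The two sets may overlap (a pathway can be linked to both
#' descriptors and toxicity). The statistic and permutation scheme are this
#' package's formalization of map proximity; the \code{note} slot records
#' that.
#'
#' @param dendrogram an \code{hclust} over pathways (from
#'   \code{\link{clusterPathways}}).
#' @param pcfLinked,toxLinked character subsets of the tree's leaves.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return A \linkS4class{MapAssociation}.
#' @export
associationTest <- function(dendrogram, pcfLinked, toxLinked, nPerm = 10000,
                            seed = 1) {
  leaves <- dendrogram$labels
  if (!length(pcfLinked) || !length(toxLinked))
    stop("both pathway sets must be non-empty")
  if (!all(pcfLinked %in% leaves) || !all(toxLinked %in% leaves))
    stop("pathway sets must be subsets of the tree's leaves")
  if (length(pcfLinked) == 1L && identical(sort(pcfLinked), sort(toxLinked)))
    stop("identical singleton sets have no pairwise distance")
  cph <- as.matrix(stats::cophenetic(dendrogram))
  statOf <- function(a, b) mean(cph[a, b, drop = FALSE])
  obs <- statOf(pcfLinked, toxLinked)
  nPerm <- as.integer(nPerm)
  nullStats <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    a <- sample(leaves, length(pcfLinked))
    b <- sample(leaves, length(toxLinked))
    statOf(a, b)
  }, numeric(1)))
  p <- (1 + sum(nullStats <= obs)) / (nPerm + 1)
  new("MapAssociation", statistic = obs, pValue = p, nPerm = nPerm,
      nullMean = mean(nullStats), nullSd = stats::sd(nullStats),
      seed = as.integer(seed),
      note = paste("mean pairwise cophenetic distance with uniform label",
                   "permutation; a package-defined formalization of map",
                   "proximity"))
}

#' Write the pathway-map artifacts
#'
#' Similarity matrix TSV, dendrogram Newick, a red/blue-style annotation
#' overlay (pathway, pcf_linked, tox_linked) and the association report JSON.
#'
#' @param similarity a \linkS4class{PathwaySimilarity}.
#' @param clustering result of \code{\link{clusterPathways}}.
#' @param association a \linkS4class{MapAssociation} (or NULL to skip).
#' @param pcfLinked,toxLinked character pathway sets for the overlay.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writePathwayMap <- function(similarity, clustering, association, pcfLinked,
                            toxLinked, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(similarityValues(similarity), file.path(dir, "jaccard_similarity.tsv"),
           rowLabel = "pathway")
  writeDendrogram(clustering$hclust, file.path(dir, "pathway_dendrogram.nwk"))
  leaves <- clustering$hclust$labels
  writeTsv(data.frame(pathway = leaves,
                      pcf_linked = as.integer(leaves %in% pcfLinked),
                      tox_linked = as.integer(leaves %in% toxLinked),
                      stringsAsFactors = FALSE),
           file.path(dir, "map_annotation.tsv"))
  if (!is.null(association))
    jsonlite::write_json(
      list(statistic = association@statistic, p_value = association@pValue,
           n_perm = association@nPerm, null_mean = association@nullMean,
           null_sd = association@nullSd, seed = association@seed,
           cophenetic_r = clustering$copheneticR, note = association@note),
      file.path(dir, "map_association.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
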