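# Accessor generics and show methods.

#' Expression matrix of a study
#' @param object an \linkS4class{ExpressionStudy}.
#' @return numeric genes x samples matrix.
#' @export
setGeneric("exprsMatrix", function(object) standardGeneric("exprsMatrix"))

#' @rdname exprsMatrix
#' @export
setMethod("exprsMatrix", "ExpressionStudy", function(object)
  SummarizedExperiment::assay(object, "exprs"))

#' Per-sample metadata of a study
#' @param object an \linkS4class{ExpressionStudy}.
#' @return data.frame with compound_id, role, match_group, toxicity.
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "ExpressionStudy", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' Treated compound identifiers of a study
#' @param object an \linkS4class{ExpressionStudy}.
#' @return character vector of unique compound ids with treated samples.
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "ExpressionStudy", function(object) {
  cd <- sampleMeta(object)
  unique(cd$compound_id[cd$role == "treated"])
})

#' Per-compound toxicity labels (treated compounds)
#' @param object an \linkS4class{ExpressionStudy}.
#' @return named character vector, compound id -> toxic/nontoxic.
#' @export
setGeneric("toxicityLabels", function(object) standardGeneric("toxicityLabels"))

#' @rdname toxicityLabels
#' @export
setMethod("toxicityLabels", "ExpressionStudy", function(object) {
  cd <- sampleMeta(object)
  cd <- cd[cd$role == "treated", ]
  lab <- tapply(cd$toxicity, cd$compound_id, function(x) x[1])
  stats::setNames(as.character(lab), names(lab))[compoundIds(object)]
})

#' Member gene sets of a collection
#' @param object a \linkS4class{GeneSetCollection}.
#' @return named list of character member vectors.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' Category labels of a collection
#' @param object a \linkS4class{GeneSetCollection}.
#' @return named character vector of per-set category labels.
#' @export
setGeneric("setCategories", function(object) standardGeneric("setCategories"))

#' @rdname setCategories
#' @export
setMethod("setCategories", "GeneSetCollection", function(object) object@category)

#' @describeIn GeneSetCollection number of gene sets.
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection gene-set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Descriptor values
#' @param object a \linkS4class{DescriptorMatrix}.
#' @return numeric compounds x descriptors matrix.
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))

#' @rdname descriptorValues
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(object) object@values)

#' Descriptor group annotation
#' @param object a \linkS4class{DescriptorMatrix}.
#' @return named character vector descriptor id -> group label.
#' @export
setGeneric("descriptorGroups", function(object) standardGeneric("descriptorGroups"))

#' @rdname descriptorGroups
#' @export
setMethod("descriptorGroups", "DescriptorMatrix", function(object) object@groups)

#' Pathway score matrices of an index set
#' @param object a \linkS4class{PathwayIndexSet}.
#' @param pathway optional single pathway id.
#' @return list of score matrices, or one matrix when \code{pathway} is given.
#' @export
setGeneric("pathwayScores", function(object, pathway = NULL)
  standardGeneric("pathwayScores"))

#' @rdname pathwayScores
#' @export
setMethod("pathwayScores", "PathwayIndexSet", function(object, pathway = NULL) {
  if (is.null(pathway)) object@scores else object@scores[[pathway]]
})

#' Retained pathway identifiers
#' @param object a \linkS4class{PathwayIndexSet}.
#' @return character vector.
#' @export
setGeneric("retainedPathways", function(object) standardGeneric("retainedPathways"))

#' @rdname retainedPathways
#' @export
setMethod("retainedPathways", "PathwayIndexSet", function(object)
  names(object@scores))

#' Perturbation index values
#' @param object a \linkS4class{PerturbationMatrix}.
#' @return numeric drugs x pathways matrix of T2 values.
#' @export
setGeneric("perturbationValues", function(object)
  standardGeneric("perturbationValues"))

#' @rdname perturbationValues
#' @export
setMethod("perturbationValues", "PerturbationMatrix", function(object) object@t2)

#' Result table of a differential analysis
#' @param object a \linkS4class{DifferentialResult}.
#' @return data.frame, one row per tested pathway.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname resultTable
#' @export
setMethod("resultTable", "DifferentialResult", function(object) object@table)

#' Selected (significant) pathways
#' @param object a \linkS4class{DifferentialResult}.
#' @return character pathway ids with q-value below the FDR level.
#' @export
setGeneric("selectedPathways", function(object) standardGeneric("selectedPathways"))

#' @rdname selectedPathways
#' @export
setMethod("selectedPathways", "DifferentialResult", function(object)
  object@table$pathway[object@table$selected])

#' Similarity values of a pathway map
#' @param object a \linkS4class{PathwaySimilarity}.
#' @return symmetric numeric matrix of Jaccard indices.
#' @export
setGeneric("similarityValues", function(object) standardGeneric("similarityValues"))

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "PathwaySimilarity", function(object) object@sim)

#' Fitted models of a population
#' @param object a \linkS4class{ModelPopulation}.
#' @return list of \linkS4class{Eq1Model}, best first.
#' @export
setGeneric("populationModels", function(object) standardGeneric("populationModels"))

#' @rdname populationModels
#' @export
setMethod("populationModels", "ModelPopulation", function(object) object@models)

#' Is the pathway flagged as PCF-linked?
#' @param object a \linkS4class{ModelPopulation}.
#' @return logical.
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))

#' @rdname isFlagged
#' @export
setMethod("isFlagged", "ModelPopulation", function(object) object@flagged)

setMethod("show", "ExpressionStudy", function(object) {
  cd <- sampleMeta(object)
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  treated samples:", sum(cd$role == "treated"),
      " control samples:", sum(cd$role == "control"), "\n")
  cat("  compounds:", length(compoundIds(object)),
      " (toxic:", sum(toxicityLabels(object) == "toxic"), ")\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection:", length(object@sets), "sets,",
      length(unique(unlist(object@sets, use.names = FALSE))), "distinct genes\n")
  cat("  set sizes:", min(sz), "-", max(sz), "\n")
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat("DescriptorMatrix:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors in",
      length(unique(object@groups)), "groups\n")
})

setMethod("show", "PathwayIndexSet", function(object) {
  cat("PathwayIndexSet:", length(object@scores), "retained pathways,",
      nrow(object@excluded), "excluded\n")
  if (length(object@cumVar))
    cat("  median cumulative variance of retained PCs:",
        round(stats::median(object@cumVar), 3), "\n")
})

setMethod("show", "PerturbationMatrix", function(object) {
  cat("PerturbationMatrix:", nrow(object@t2), "drugs x", ncol(object@t2),
      "pathways;", sum(is.na(object@t2)), "cells unavailable\n")
})

setMethod("show", "DifferentialResult", function(object) {
  cat("DifferentialResult:", nrow(object@table), "pathways tested,",
      sum(object@table$selected), "selected at FDR", object@fdrLevel, "\n")
})

setMethod("show", "Eq1Model", function(object) {
  cat("Eq1Model", if (!is.na(object@pathwayId)) paste0("[", object@pathwayId, "]"),
      "PC", object@pcIndex, ": ", paste(object@triple, collapse = " + "), "\n")
  cat("  train R2 =", round(object@trainR2, 3),
      " CV R2 =", round(object@cvR2, 3),
      " test R2 =", round(object@testR2, 3), "\n")
})

setMethod("show", "ModelPopulation", function(object) {
  cat("ModelPopulation for", object@pathwayId, ":", length(object@models),
      "models;", if (object@flagged) "PCF-linked" else "not flagged", "\n")
})

setMethod("show", "PathwaySimilarity", function(object) {
  cat("PathwaySimilarity:", nrow(object@sim), "pathways\n")
})

setMethod("show", "MapAssociation", function(object) {
  cat("MapAssociation: statistic =", signif(object@statistic, 4),
      ", p =", signif(object@pValue, 4), "(", object@nPerm, "permutations )\n")
})

setMethod("show", "MLHDModel", function(object) {
  cat("MLHDModel:", length(object@classes), "classes,",
      length(object@features), "features",
      if (object@ridged) "(ridged covariance)" else "", "\n")
})

setMethod("show", "FeatureSplit", function(object) {
  cat("FeatureSplit: linked =", length(object@linked),
      ", uncorrelated =", length(object@uncorrelated),
      "(|r| <", object@corCutoff, ")\n")
})
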