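#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.ROLES <- c("treated", "control")
.TOX <- c("toxic", "nontoxic", "na")

#' ExpressionStudy: a genes x samples expression study with sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay \code{"exprs"}
#' holds real-valued (log-scale, already normalized) expression; \code{colData}
#' carries per-sample metadata: \code{compound_id}, \code{role} (treated /
#' control), \code{match_group} (links each treated sample to its control
#' group) and \code{toxicity} (toxic / nontoxic / na).
#'
#' Validity requires unique gene and sample identifiers, no missing values,
#' a toxicity label for every treated sample, and at least two control samples
#' in every treated sample's match group.
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  m <- SummarizedExperiment::assay(object, "exprs")
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  msgs <- character()
  need <- c("compound_id", "role", "match_group", "toxicity")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(m))) msgs <- c(msgs, "gene ids must be unique")
  if (anyDuplicated(colnames(m))) msgs <- c(msgs, "sample ids must be unique")
  if (anyNA(m)) msgs <- c(msgs, "expression matrix contains missing values")
  if (!all(cd$role %in% .ROLES))
    msgs <- c(msgs, "role must be 'treated' or 'control'")
  if (!all(cd$toxicity %in% .TOX))
    msgs <- c(msgs, "toxicity must be 'toxic', 'nontoxic' or 'na'")
  tr <- cd$role == "treated"
  if (any(tr & !(cd$toxicity %in% c("toxic", "nontoxic"))))
    msgs <- c(msgs, "every treated sample needs a toxicity label")
  for (g in unique(cd$match_group[tr])) {
    nCtl <- sum(cd$match_group == g & cd$role == "control")
    if (nCtl < 2) {
      msgs <- c(msgs, sprintf("match group '%s' has %d control samples (needs >= 2)",
                              g, nCtl))
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param sampleMeta data.frame with one row per sample (rownames or a
#'   \code{sample_id} column matching \code{colnames(exprs)}) and columns
#'   \code{compound_id}, \code{role}, \code{match_group}, \code{toxicity}.
#' @return An \linkS4class{ExpressionStudy}.
#' @export
ExpressionStudy <- function(exprs, sampleMeta) {
  exprs <- as.matrix(exprs)
  sampleMeta <- as.data.frame(sampleMeta, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(sampleMeta)) {
    rownames(sampleMeta) <- sampleMeta$sample_id
    sampleMeta$sample_id <- NULL
  }
  missing <- setdiff(colnames(exprs), rownames(sampleMeta))
  if (length(missing))
    stop("samples present in the matrix but absent from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sampleMeta <- sampleMeta[colnames(exprs), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(sampleMeta))
  new("ExpressionStudy", se)
}

#' GeneSetCollection: named gene sets with category labels
#'
#' A lightweight container for a gene-set collection (e.g. a KEGG-pathway
#' stand-in read from GMT). Duplicate members within a set are collapsed at
#' construction; a gene may belong to many sets.
#'
#' @slot sets named list of character vectors of member gene ids.
#' @slot category character vector of per-set category labels (same length).
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", category = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) == 0L) return("collection contains no gene sets")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("gene sets must have unique names")
  if (length(object@category) != length(object@sets))
    return("category labels must match the number of sets")
  if (!all(vapply(object@sets, is.character, logical(1))))
    return("set members must be character gene ids")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    return("duplicate members within a set must be collapsed")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character member vectors (duplicates collapsed).
#' @param category optional per-set category labels; defaults to "".
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, category = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(category)) category <- rep("", length(sets))
  category <- as.character(category)
  names(category) <- names(sets)
  new("GeneSetCollection", sets = sets, category = category)
}

#' DescriptorMatrix: compounds x physico-chemical descriptors
#'
#' Real-valued descriptor values for a panel of compounds, plus a mapping of
#' every descriptor to exactly one descriptor group (e.g. "RDF descriptors",
#' "WHIM descriptors"). Missing values are disallowed: descriptors that cannot
#' be computed for all compounds are dropped at read time.
#'
#' @slot values numeric matrix, compounds in rows, descriptors in columns.
#' @slot groups named character vector, descriptor id -> group label.
#' @export
setClass("DescriptorMatrix",
         representation(values = "matrix", groups = "character"))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  if (anyNA(v)) return("descriptor matrix contains missing values")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("descriptor ids must be unique colnames")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("compound ids must be unique rownames")
  if (!setequal(names(object@groups), colnames(v)))
    return("every descriptor needs exactly one group label")
  TRUE
})

#' Construct a DescriptorMatrix
#' @param values numeric compounds x descriptors matrix.
#' @param groups named character vector mapping descriptor ids to group labels.
#' @return A \linkS4class{DescriptorMatrix}.
#' @export
DescriptorMatrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- groups[colnames(values)]
  new("DescriptorMatrix", values = values,
      groups = stats::setNames(as.character(groups), colnames(values)))
}

#' PathwayIndexSet: per-pathway principal-component activity indices
#'
#' For each retained pathway: the sample scores on the retained principal
#' components, the gene loadings, the per-component variance fractions and the
#' gene count. Pathways excluded by the size rule or by degeneracy are recorded
#' with their reason.
#'
#' @slot scores named list of samples x retained-PC score matrices.
#' @slot loadings named list of genes x retained-PC loading matrices.
#' @slot varFrac named list of per-PC variance fractions (retained PCs).
#' @slot cumVar named numeric: cumulative variance fraction of the retained PCs.
#' @slot nGenes named integer: matched gene count per retained pathway.
#' @slot excluded data.frame(pathway, reason).
#' @slot belowTarget character: pathways whose retained PCs fall short of the
#'   variance target (capped by \code{maxPcs}).
#' @slot params list: minGenes, varianceTarget, maxPcs, scaled.
#' @slot sampleIds character sample ordering shared by all score matrices.
#' @export
setClass("PathwayIndexSet",
         representation(scores = "list", loadings = "list", varFrac = "list",
                        cumVar = "numeric", nGenes = "integer",
                        excluded = "data.frame", belowTarget = "character",
                        params = "list", sampleIds = "character"))

setValidity("PathwayIndexSet", function(object) {
  for (nm in names(object@varFrac)) {
    v <- object@varFrac[[nm]]
    if (any(v <= 0 | v > 1 + 1e-12))
      return(sprintf("variance fractions of '%s' outside (0,1]", nm))
    if (is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 1e-12))
      return(sprintf("variance fractions of '%s' not non-increasing", nm))
  }
  if (any(object@nGenes <= 5L))
    return("retained pathways must have more than 5 matched genes")
  TRUE
})

#' SyntheticTruth: planted ground truth of a synthetic study
#'
#' Records everything the generator planted: which pathways carry a
#' toxicity-linked differential signal, which are linked to descriptor triples
#' (and with what coefficients), the per-compound latent factor values and
#' toxicity labels, the loading vectors, noise levels and the seed. Downstream
#' recovery tests compare estimates against these fields.
#'
#' @slot differential character ids of planted differential pathways.
#' @slot linked character ids of descriptor-linked (causal) pathways.
#' @slot toxicity named character per-compound labels.
#' @slot toxFactor named numeric: toxicity-linked latent factor per compound.
#' @slot factor1 named numeric: non-specific (dose-like) factor per compound.
#' @slot factor2 numeric matrix compounds x pathways of factor-2 values.
#' @slot loadings list per pathway: list(l1, l2) gene loading vectors.
#' @slot triples named list pathway -> character(3) causal descriptor ids.
#' @slot coefficients named list pathway -> named numeric(7) a..g.
#' @slot effectSize,noiseSd,linkStrength numeric generator settings.
#' @slot seed integer.
#' @export
setClass("SyntheticTruth",
         representation(differential = "character", linked = "character",
                        toxicity = "character", toxFactor = "numeric",
                        factor1 = "numeric", factor2 = "matrix",
                        loadings = "list", triples = "list",
                        coefficients = "list", effectSize = "numeric",
                        noiseSd = "numeric", linkStrength = "numeric",
                        seed = "integer"))

#' PerturbationMatrix: drug x pathway Hotelling T2 perturbation indices
#'
#' @slot t2 numeric drugs x pathways matrix of T2 values (NA where the
#'   statistic could not be computed).
#' @slot issues data.frame(drug, pathway, message) log of per-cell failures.
#' @slot params list (number of PCs used, group sizes).
#' @export
setClass("PerturbationMatrix",
         representation(t2 = "matrix", issues = "data.frame", params = "list"))

setValidity("PerturbationMatrix", function(object) {
  if (any(object@t2 < -1e-12, na.rm = TRUE)) return("T2 values must be >= 0")
  TRUE
})

#' DifferentialResult: toxic vs non-toxic differential pathway modulation
#'
#' One row per tested pathway: Hotelling T2, its F transform, p-value,
#' Benjamini-Hochberg q-value, the selection flag at the configured FDR level
#' and per-PC univariate t statistics.
#'
#' @slot table data.frame with columns pathway, n_genes, T2, F, df1, df2,
#'   p_value, q_value, selected, t_pc1, t_pc2.
#' @slot fdrLevel numeric FDR level used for selection.
#' @export
setClass("DifferentialResult",
         representation(table = "data.frame", fdrLevel = "numeric"))

setValidity("DifferentialResult", function(object) {
  q <- object@table$q_value
  if (any(q < 0 | q > 1, na.rm = TRUE)) return("q-values must lie in [0,1]")
  TRUE
})

#' Eq1Model: one three-descriptor interaction regression
#'
#' The model \deqn{PC_{ik} = a + b D_1 + c D_2 + d D_3 + e D_1 D_2 +
#' f D_1 D_3 + g D_2 D_3 + \epsilon} linking a pathway activity component to
#' three descriptors and their pairwise interactions.
#'
#' @slot pathwayId character (may be NA).
#' @slot pcIndex integer: which pathway PC is modelled (2 by default upstream).
#' @slot triple character(3) descriptor ids.
#' @slot coefficients named numeric(7): a, b, c, d, e, f, g.
#' @slot trainR2,cvR2,testR2 numeric fit statistics (NA when not computed).
#' @slot sigma2 numeric residual variance estimate.
#' @export
setClass("Eq1Model",
         representation(pathwayId = "character", pcIndex = "integer",
                        triple = "character", coefficients = "numeric",
                        trainR2 = "numeric", cvR2 = "numeric",
                        testR2 = "numeric", sigma2 = "numeric"))

setValidity("Eq1Model", function(object) {
  if (length(object@triple) != 3L || anyDuplicated(object@triple))
    return("triple must contain three distinct descriptors")
  if (!all(is.finite(object@coefficients)))
    return("coefficients must be finite")
  if (is.finite(object@cvR2) && object@cvR2 > 1 + 1e-12)
    return("cross-validated R2 cannot exceed 1")
  TRUE
})

#' ModelPopulation: the population of Eq1 models found for one pathway
#'
#' @slot pathwayId character.
#' @slot models list of \linkS4class{Eq1Model}, sorted by non-increasing
#'   cross-validated fitness.
#' @slot settings list snapshot of the GA settings.
#' @slot seed integer.
#' @slot flagged logical: TRUE when at least one model reaches the fitness
#'   threshold (the pathway is "PCF-linked").
#' @export
setClass("ModelPopulation",
         representation(pathwayId = "character", models = "list",
                        settings = "list", seed = "integer",
                        flagged = "logical"))

setValidity("ModelPopulation", function(object) {
  f <- vapply(object@models, function(m) m@cvR2, numeric(1))
  if (length(f) > 1 && any(diff(f) > 1e-12))
    return("models must be sorted by non-increasing fitness")
  TRUE
})

#' PathwaySimilarity: Jaccard overlap between gene sets
#'
#' @slot sim symmetric pathways x pathways matrix of Jaccard indices
#'   (unit diagonal, values in [0,1]).
#' @export
setClass("PathwaySimilarity", representation(sim = "matrix"))

setValidity("PathwaySimilarity", function(object) {
  s <- object@sim
  if (nrow(s) != ncol(s)) return("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-12) return("similarity matrix must be symmetric")
  if (any(s < -1e-12 | s > 1 + 1e-12)) return("Jaccard values must lie in [0,1]")
  if (max(abs(diag(s) - 1)) > 1e-12) return("diagonal must equal 1")
  TRUE
})

#' MapAssociation: permutation test of proximity on the pathway map
#'
#' @slot statistic observed mean cophenetic distance between the two label sets.
#' @slot pValue permutation p-value, resolution 1/(nPerm+1).
#' @slot nPerm integer number of permutations.
#' @slot nullMean,nullSd numeric summary of the permutation null.
#' @slot seed integer.
#' @slot note character: documents that the statistic/null construction is this
#'   package's formalization of map proximity.
#' @export
setClass("MapAssociation",
         representation(statistic = "numeric", pValue = "numeric",
                        nPerm = "integer", nullMean = "numeric",
                        nullSd = "numeric", seed = "integer", note = "character"))

#' MLHDModel: maximum-likelihood Gaussian discriminant
#'
#' Gaussian class-conditional classifier with class means and a pooled
#' covariance; prediction assigns the class of maximal likelihood (equal priors
#' by default).
#'
#' @slot means classes x features matrix of class means.
#' @slot covInv inverse pooled covariance.
#' @slot priors named numeric class priors.
#' @slot classes character class labels.
#' @slot features character feature ids.
#' @slot ridged logical: TRUE when the pooled covariance needed ridge
#'   regularization.
#' @export
setClass("MLHDModel",
         representation(means = "matrix", covInv = "matrix",
                        priors = "numeric", classes = "character",
                        features = "character", ridged = "logical"))

#' FeatureSplit: pathway-linked vs uncorrelated descriptor subsets
#'
#' @slot linked descriptor ids appearing in any retained Eq1 model.
#' @slot uncorrelated descriptor ids outside \code{linked} whose absolute
#'   Pearson correlation with every linked descriptor is below the cutoff.
#' @slot corCutoff numeric correlation cutoff (0.5 by default).
#' @export
setClass("FeatureSplit",
         representation(linked = "character", uncorrelated = "character",
                        corCutoff = "numeric"))

setValidity("FeatureSplit", function(object) {
  if (length(intersect(object@linked, object@uncorrelated)))
    return("subsets must be disjoint")
  TRUE
})
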