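# Synthetic data generator with planted, recorded ground truth.
#
# The generator emulates the structure of a repeat-dose toxicogenomics study:
# a panel of compounds, each with a small number of treated replicates and a
# matched control group, a minority of toxic compounds, pathway-coherent
# expression covariance driven by two latent factors per pathway (a
# larger-variance non-specific "dose" factor and a toxicity-linked factor),
# and a descriptor table in which three-descriptor linear+interaction
# combinations drive the toxicity-linked factor of selected pathways.

.DESCRIPTOR_GROUPS <- c(
  "ET-state Indices", "RDF descriptors", "GSFRAG Descriptor",
  "WHIM descriptors", "GETAWAY descriptors", "Geometrical descriptors",
  "3D-MoRSE descriptors", "2D autocorrelations", "Information indices",
  "Edge adjacency indices", "Topological charge indices",
  "Molecular properties")

#' Generate a gene-set collection with block overlap structure
#'
#' Sets are assigned contiguously to \code{nBlocks} blocks. Sets within a block
#' share a common core of genes (size \code{round(coreFraction *
#' min(sizeRange))}) so within-block Jaccard overlap is substantial, while
#' blocks use disjoint gene pools so across-block overlap is exactly zero.
#' This emulates the clustered overlap structure of a curated pathway database
#' and makes the Jaccard pathway map non-trivial.
#'
#' @param nSets number of gene sets.
#' @param sizeRange integer range of set sizes; the minimum must be >= 6
#'   because downstream pathway summarization requires more than 5 genes.
#' @param nBlocks number of overlap blocks.
#' @param coreFraction fraction of the minimum set size shared as a block core.
#' @param seed integer seed; the seed fully determines the output.
#' @return A \linkS4class{GeneSetCollection} with per-set block categories.
#' @export
generateGeneSets <- function(nSets, sizeRange = c(10, 24), nBlocks = 4,
                             coreFraction = 0.5, seed = 1) {
  if (sizeRange[1] < 6) stop("set sizes below 6 are not allowed")
  if (nSets < 1) stop("need at least one set")
  nBlocks <- max(1L, min(as.integer(nBlocks), nSets))
  withSeed(seed, {
    block <- rep(seq_len(nBlocks), each = ceiling(nSets / nBlocks))[seq_len(nSets)]
    sizes <- sample(seq(sizeRange[1], sizeRange[2]), nSets, replace = TRUE)
    coreSize <- round(coreFraction * sizeRange[1])
    counter <- 0L
    newGenes <- function(k) {
      ids <- sprintf("g%05d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    cores <- lapply(seq_len(nBlocks), function(b) newGenes(coreSize))
    sets <- vector("list", nSets)
    for (i in seq_len(nSets)) {
      core <- cores[[block[i]]]
      own <- newGenes(max(0L, sizes[i] - length(core)))
      sets[[i]] <- c(core, own)
    }
    names(sets) <- sprintf("PW%03d", seq_len(nSets))
    GeneSetCollection(sets, category = sprintf("block%02d", block))
  })
}

#' Generate a synthetic expression study with planted pathway signals
#'
#' Expression of a gene in pathway k is
#' \deqn{x_{gs} = \mu_g + l_{1g} f_1(c) + l_{2g} f_{2k}(c) + N(0, noiseSd)}
#' for treated samples of compound c, and \eqn{\mu_g + N(0, noiseSd)} for the
#' matched controls (latent factors 0). \eqn{f_1} is a compound-level
#' non-specific (dose-like) factor with standard deviation \code{factor1Sd};
#' \eqn{f_{2k}} is the pathway's toxicity-linked factor. The first
#' \code{nDifferential} pathways share a common toxicity factor whose mean
#' differs by \code{effectSize} between toxic and non-toxic compounds; all
#' other pathways get independent standard-normal factors with no toxicity
#' link. Because \code{factor1Sd} exceeds the toxicity factor scale, pathway
#' PCA places the non-specific signal on PC1 and the toxicity-linked signal on
#' PC2. Every gene carries a single loading pair: the non-specific factor
#' loads on all genes, while a pathway's specific factor loads only on the
#' genes unique to that set -- genes shared between sets (the block backbone)
#' respond to the dose factor alone, so pathway-specific signals are
#' independent across sets.
#'
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param nCompounds number of treated compounds.
#' @param fracToxic fraction of toxic compounds, in (0, 1).
#' @param nReps treated replicates per compound (>= 2); controls match.
#' @param effectSize mean shift of the toxicity factor between classes, in
#'   units of its unit residual standard deviation.
#' @param noiseSd gene-level measurement noise standard deviation.
#' @param nDifferential number of planted differential pathways.
#' @param factor1Sd standard deviation of the non-specific factor.
#' @param loadingRange absolute loading range for both factors.
#' @param nullFactorSd standard deviation of the specific factors of
#'   non-differential pathways (default 1; 0 plants no pathway-specific
#'   activity outside the differential set).
#' @param seed integer seed.
#' @return list with elements \code{study} (\linkS4class{ExpressionStudy}) and
#'   \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
generateStudy <- function(geneSets, nCompounds = 40, fracToxic = 0.25,
                          nReps = 3, effectSize = 3, noiseSd = 1,
                          nDifferential = 10, factor1Sd = 3,
                          loadingRange = c(0.7, 1.2), nullFactorSd = 1,
                          seed = 1) {
  if (nReps < 2) stop("nReps must be >= 2")
  if (fracToxic <= 0 || fracToxic >= 1) stop("fracToxic must lie in (0, 1)")
  sets <- geneSets(geneSets)
  nSets <- length(sets)
  if (nDifferential > nSets) stop("more differential pathways than sets")
  withSeed(seed, {
    compounds <- sprintf("C%03d", seq_len(nCompounds))
    nToxic <- round(fracToxic * nCompounds)
    toxicity <- rep("nontoxic", nCompounds)
    toxicity[sample.int(nCompounds, nToxic)] <- "toxic"
    names(toxicity) <- compounds
    toxFactor <- effectSize * (toxicity == "toxic") + stats::rnorm(nCompounds)
    names(toxFactor) <- compounds
    factor1 <- stats::rnorm(nCompounds, 0, factor1Sd)
    names(factor1) <- compounds

    pwIds <- names(sets)
    differential <- pwIds[seq_len(nDifferential)]
    factor2 <- matrix(0, nCompounds, nSets, dimnames = list(compounds, pwIds))
    for (k in seq_len(nSets)) {
      factor2[, k] <- if (pwIds[k] %in% differential) toxFactor
                      else if (nullFactorSd > 0)
                        stats::rnorm(nCompounds, 0, nullFactorSd)
                      else rep(0, nCompounds)
    }

    # every gene carries a single loading pair; the non-specific factor loads
    # on all genes, while a set's specific factor loads only on the genes
    # unique to that set (shared backbone genes respond to dose alone), so
    # pathway-specific signals are independent across sets
    universe <- unique(unlist(sets, use.names = FALSE))
    G <- length(universe)
    membership <- table(unlist(sets, use.names = FALSE))
    shared <- names(membership)[membership > 1L]
    owner <- integer(G)
    for (k in rev(seq_len(nSets))) owner[match(sets[[k]], universe)] <- k
    l1 <- stats::runif(G, loadingRange[1], loadingRange[2]) *
      sample(c(-1, 1), G, replace = TRUE)
    l2 <- stats::runif(G, loadingRange[1], loadingRange[2]) *
      sample(c(-1, 1), G, replace = TRUE)
    names(l1) <- names(l2) <- universe
    l2[shared] <- 0
    loadings <- vector("list", nSets)
    names(loadings) <- pwIds
    for (k in seq_len(nSets)) {
      loadings[[k]] <- list(l1 = l1[sets[[k]]], l2 = l2[sets[[k]]])
      if (pwIds[k] %in% differential && all(loadings[[k]]$l2 == 0))
        stop("differential pathway with all-zero loadings: ", pwIds[k])
    }

    mu <- stats::rnorm(G, 7, 1)
    eff <- outer(l1, factor1) + l2 * t(factor2[, owner, drop = FALSE])
    dimnames(eff) <- list(universe, compounds)

    nSamples <- nCompounds * nReps * 2L
    sampleIds <- character(nSamples)
    meta <- data.frame(compound_id = character(nSamples),
                       role = character(nSamples),
                       match_group = character(nSamples),
                       toxicity = character(nSamples),
                       stringsAsFactors = FALSE)
    x <- matrix(0, G, nSamples, dimnames = list(universe, NULL))
    col <- 0L
    for (c in seq_len(nCompounds)) {
      cid <- compounds[c]
      for (r in seq_len(nReps)) {
        col <- col + 1L
        sampleIds[col] <- sprintf("%s_T%d", cid, r)
        meta[col, ] <- list(cid, "treated", cid, toxicity[[cid]])
        x[, col] <- mu + eff[, c]
      }
      for (r in seq_len(nReps)) {
        col <- col + 1L
        sampleIds[col] <- sprintf("%s_C%d", cid, r)
        meta[col, ] <- list(cid, "control", cid, "na")
        x[, col] <- mu
      }
    }
    if (noiseSd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, noiseSd), nrow(x))
    colnames(x) <- sampleIds
    rownames(meta) <- sampleIds

    study <- ExpressionStudy(x, meta)
    truth <- new("SyntheticTruth",
                 differential = differential, linked = character(),
                 toxicity = toxicity, toxFactor = toxFactor,
                 factor1 = factor1, factor2 = factor2, loadings = loadings,
                 triples = list(), coefficients = list(),
                 effectSize = effectSize, noiseSd = noiseSd,
                 linkStrength = NA_real_, seed = as.integer(seed))
    list(study = study, truth = truth)
  })
}

#' Generate a descriptor matrix whose triples drive pathway factors
#'
#' For each of the first \code{nLinked} planted differential pathways a causal
#' descriptor triple is created such that the pathway's toxicity-linked factor
#' satisfies \deqn{f_2(c) = a + b D_1 + c D_2 + d D_3 + e D_1 D_2 + \epsilon}
#' exactly, with \eqn{var(\epsilon) = (1 - linkStrength) \cdot var(f_2)}:
#' \eqn{D_1, D_2} are standard normal, the interaction coefficient e dominates
#' (so interaction terms carry at least half of the explained variance), and
#' \eqn{D_3} is solved from the identity. The two remaining pairwise
#' interaction coefficients (f, g) are planted at zero. All other descriptors
#' are independent noise. Descriptor columns are shuffled and assigned
#' round-robin to named descriptor groups.
#'
#' @param study the \linkS4class{ExpressionStudy} the factors belong to.
#' @param truth the \linkS4class{SyntheticTruth} from \code{generateStudy}.
#' @param nDescriptors total number of descriptors (>= 9, and >= 3 * nLinked).
#' @param nGroups number of descriptor groups (vocabulary of 12 field names,
#'   extended generically beyond that).
#' @param linkStrength fraction of the factor variance explained by the causal
#'   triple, in [0, 1].
#' @param nLinked number of descriptor-linked pathways (taken from the planted
#'   differential pathways).
#' @param descriptorCor correlation of causal D1/D2 descriptors to their
#'   shared family components, in [0, 1). Real descriptor panels are heavily
#'   inter-correlated within families; this is also what lets the downstream
#'   correlation rule recognize causal descriptors that were not themselves
#'   selected in a model.
#' @param seed integer seed.
#' @return list with elements \code{descriptors}
#'   (\linkS4class{DescriptorMatrix}) and \code{truth} (updated with linked
#'   pathways, causal triples and coefficients).
#' @export
generateDescriptors <- function(study, truth, nDescriptors = 60, nGroups = 12,
                                linkStrength = 0.9, nLinked = 8,
                                descriptorCor = 0.85, seed = 1) {
  if (linkStrength < 0 || linkStrength > 1)
    stop("linkStrength must lie in [0, 1]")
  if (nDescriptors < 9) stop("need at least 9 descriptors")
  if (3 * nLinked > nDescriptors)
    stop("nDescriptors too small for ", nLinked, " causal triples")
  if (nLinked > length(truth@differential))
    stop("cannot link more pathways than were planted differential")
  compounds <- compoundIds(study)
  if (!identical(sort(compounds), sort(names(truth@toxFactor))))
    stop("study and truth describe different compound panels")
  n <- length(compounds)
  if (descriptorCor < 0 || descriptorCor >= 1)
    stop("descriptorCor must lie in [0, 1)")
  withSeed(seed, {
    linked <- truth@differential[seq_len(nLinked)]
    cols <- matrix(stats::rnorm(n * nDescriptors), n, nDescriptors)
    triples <- list()
    coefs <- list()
    pos <- 0L
    # causal D1/D2 columns are drawn around shared family components, the way
    # real descriptor families are inter-correlated; this is also what lets
    # the downstream |r| >= 0.5 rule recognize causal descriptors that were
    # not themselves selected in a model
    u1 <- stats::rnorm(n)
    u2 <- stats::rnorm(n)
    rho <- descriptorCor
    for (pw in linked) {
      f2 <- truth@factor2[compounds, pw]
      D1 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n)
      D2 <- rho * u2 + sqrt(1 - rho^2) * stats::rnorm(n)
      a <- stats::rnorm(1, 0, 0.2)
      b <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.3)
      cc <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.3)
      d <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2)
      e <- sample(c(-1, 1), 1) * stats::runif(1, 2.0, 2.6)
      sigma <- sqrt((1 - linkStrength) * stats::var(f2))
      eps <- if (sigma > 0) stats::rnorm(n, 0, sigma) else numeric(n)
      D3 <- (f2 - eps - a - b * D1 - cc * D2 - e * D1 * D2) / d
      cols[, pos + 1L] <- D1
      cols[, pos + 2L] <- D2
      cols[, pos + 3L] <- D3
      triples[[pw]] <- pos + 1:3
      coefs[[pw]] <- c(a = a, b = b, c = cc, d = d, e = e, f = 0, g = 0)
      pos <- pos + 3L
    }
    perm <- sample.int(nDescriptors)          # new column position of column i
    ids <- sprintf("D%04d", seq_len(nDescriptors))
    values <- matrix(0, n, nDescriptors, dimnames = list(compounds, ids))
    values[, perm] <- cols
    groupNames <- if (nGroups <= length(.DESCRIPTOR_GROUPS))
      .DESCRIPTOR_GROUPS[seq_len(nGroups)]
    else c(.DESCRIPTOR_GROUPS,
           sprintf("Descriptor group %d", seq_len(nGroups - length(.DESCRIPTOR_GROUPS))))
    groups <- stats::setNames(rep_len(groupNames, nDescriptors), ids)
    triples <- lapply(triples, function(idx) ids[perm[idx]])
    truth@linked <- linked
    truth@triples <- triples
    truth@coefficients <- coefs
    truth@linkStrength <- linkStrength
    list(descriptors = DescriptorMatrix(values, groups), truth = truth)
  })
}

truthToList <- function(truth) {
  list(differential = truth@differential,
       linked = truth@linked,
       toxicity = as.list(truth@toxicity),
       toxFactor = as.list(truth@toxFactor),
       factor1 = as.list(truth@factor1),
       triples = truth@triples,
       coefficients = lapply(truth@coefficients, as.list),
       effectSize = truth@effectSize,
       noiseSd = truth@noiseSd,
       linkStrength = truth@linkStrength,
       seed = truth@seed)
}

#' Write the synthetic inputs and ground truth to a directory
#'
#' Emits the three pipeline input artifacts in their interchange formats
#' (expression.tsv + samples.tsv, genesets.gmt, descriptors.tsv +
#' descriptor_groups.tsv) plus truth.json recording the planted ground truth.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticInputs <- function(study, geneSets, descriptors, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionStudy(study, file.path(dir, "expression.tsv"),
                       file.path(dir, "samples.tsv"))
  writeGmt(geneSets, file.path(dir, "genesets.gmt"))
  writeDescriptorMatrix(descriptors, file.path(dir, "descriptors.tsv"),
                        file.path(dir, "descriptor_groups.tsv"))
  jsonlite::write_json(truthToList(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
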