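# End-to-end orchestration: configuration, the run-all driver and the run
# manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults, including
#' the synthetic demo conditions (40 compounds with 3 treated replicates and
#' matched controls each, 25\% toxic, 60 pathways in 6 overlap blocks, 10
#' planted differential pathways of which 8 are descriptor-linked, effect size
#' 3 at unit noise, 60 descriptors in 12 groups).
#'
#' @return a named list (class \code{pcflink_config}).
#' @export
defaultConfig <- function() {
  cfg <- list(
    seed = 1L,
    synthetic = list(
      nSets = 60L, sizeMin = 10L, sizeMax = 24L, nBlocks = 6L,
      coreFraction = 0.5,
      nCompounds = 40L, fracToxic = 0.25, nReps = 3L, effectSize = 3,
      noiseSd = 1, nDifferential = 10L, factor1Sd = 3,
      nDescriptors = 60L, nGroups = 12L, linkStrength = 0.9, nLinked = 8L),
    index = list(minGenes = 6L, varianceTarget = 0.8, maxPcs = 2L,
                 scale = FALSE),
    differential = list(fdrLevel = 0.01),
    qspr = list(whichPc = 2L, threshold = 0.5, testR2Min = 0, cvFolds = 5L,
                split = 2 / 3,
                nRuns = 6L, population = 24L, generations = 40L,
                mutationRate = 1 / 3, goalFitness = Inf),
    map = list(nPerm = 1999L, restrictToExpressed = TRUE),
    classifier = list(corCutoff = 0.5, kFolds = 5L, chromosomeLen = 3L,
                      nRuns = 25L, population = 20L, generations = 25L,
                      mutationRate = 1 / 3, priors = "equal"),
    inputs = NULL)
  class(cfg) <- c("pcflink_config", "list")
  cfg
}

#' Validate a pipeline configuration
#' @param config a config list.
#' @return the config, invisibly annotated, or an error.
#' @export
validateConfig <- function(config) {
  inRange <- function(x, lo, hi, what) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop("config: ", what, " must lie in [", lo, ", ", hi, "]")
  }
  inRange(config$index$varianceTarget, 0, 1, "index$varianceTarget")
  inRange(config$differential$fdrLevel, 0, 1, "differential$fdrLevel")
  inRange(config$qspr$threshold, 0, 1, "qspr$threshold")
  inRange(config$qspr$split, 0.1, 0.9, "qspr$split")
  inRange(config$classifier$corCutoff, 0, 1, "classifier$corCutoff")
  inRange(config$synthetic$fracToxic, 1e-9, 1 - 1e-9, "synthetic$fracToxic")
  if (config$index$minGenes < 1) stop("config: index$minGenes must be >= 1")
  if (config$map$nPerm < 1) stop("config: map$nPerm must be >= 1")
  if (!is.numeric(config$seed)) stop("config: seed must be an integer")
  class(config) <- c("pcflink_config", "list")
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (the synthetic generator by default,
#' or the TSV/GMT inputs named in \code{config$inputs}), pathway PCA indices,
#' drug perturbation indices with hierarchical clustering, toxic-vs-nontoxic
#' differential pathways, per-pathway GA descriptor-triple search, the Jaccard
#' pathway map with the proximity association test between descriptor-linked
#' and toxicity-linked pathways, the descriptor feature split, GA classifier
#' searches on both subsets with a Mann-Whitney comparison, and the
#' representative toxicity model. All declared artifacts are written under
#' \code{outputDir} and listed, with checksums, in the run manifest
#' (manifest.json).
#'
#' Every stochastic stage draws from a substream derived from the global seed
#' and the stage name, so individual stages are reproducible and the whole run
#' is byte-identical under a fixed config.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param outputDir output directory (created if needed).
#' @param verbose print per-stage progress counts? Default TRUE.
#' @return the run manifest, invisibly (a list; also written as JSON).
#' @export
runAll <- function(config = defaultConfig(), outputDir = tempfile("pcflink_run_"),
                   verbose = TRUE) {
  validateConfig(config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  timings <- list()
  say <- function(...) if (verbose) message(...)
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (is.null(config$inputs)) {
    sy <- config$synthetic
    gs <- clock("generate_gene_sets",
      generateGeneSets(sy$nSets, c(sy$sizeMin, sy$sizeMax), sy$nBlocks,
                       sy$coreFraction, seed = stageSeed(seed, "gene_sets")))
    st <- clock("generate_study",
      generateStudy(gs, sy$nCompounds, sy$fracToxic, sy$nReps, sy$effectSize,
                    sy$noiseSd, sy$nDifferential, sy$factor1Sd,
                    seed = stageSeed(seed, "study")))
    de <- clock("generate_descriptors",
      generateDescriptors(st$study, st$truth, sy$nDescriptors, sy$nGroups,
                          sy$linkStrength, sy$nLinked,
                          seed = stageSeed(seed, "descriptors")))
    study <- st$study; geneSetsObj <- gs
    descriptors <- de$descriptors; truth <- de$truth
    writeSyntheticInputs(study, geneSetsObj, descriptors, truth,
                         file.path(outputDir, "inputs"))
  } else {
    study <- readExpressionStudy(config$inputs$expression, config$inputs$samples)
    geneSetsObj <- readGmt(config$inputs$geneSets)
    descriptors <- readDescriptorMatrix(config$inputs$descriptors,
                                        config$inputs$descriptorGroups)
  }
  compounds <- matchCompounds(study, descriptors)
  say("inputs: ", nrow(study), " genes, ", length(compounds), " compounds, ",
      length(geneSetsObj), " gene sets, ",
      ncol(descriptorValues(descriptors)), " descriptors")

  # --- pathway indices ----------------------------------------------------
  ix <- config$index
  indexSet <- clock("pathway_indices", suppressWarnings(
    computePathwayIndices(study, geneSetsObj, ix$minGenes, ix$varianceTarget,
                          ix$maxPcs, ix$scale)))
  writePathwayIndices(indexSet, outputDir)
  say("pathway indices: ", length(retainedPathways(indexSet)), " retained")

  # --- perturbation + drug clustering -------------------------------------
  pert <- clock("perturbation", perturbationIndex(indexSet, study))
  writeTsv(perturbationValues(pert), file.path(outputDir, "perturbation_t2.tsv"),
           rowLabel = "drug")
  drugClust <- clock("cluster_drugs", clusterDrugs(pert))
  writeDendrogram(drugClust$hclust, file.path(outputDir, "drug_dendrogram.nwk"))

  # --- differential pathways ----------------------------------------------
  diffRes <- clock("differential",
    differentialPathways(indexSet, study, config$differential$fdrLevel))
  writeTsv(resultTable(diffRes), file.path(outputDir, "differential_pathways.tsv"))
  sel <- resultTable(diffRes)[resultTable(diffRes)$selected,
                              c("pathway", "n_genes", "T2")]
  writeTsv(sel, file.path(outputDir, "selected_pathways.tsv"))
  toxLinked <- selectedPathways(diffRes)
  say("differential pathways at FDR ", config$differential$fdrLevel, ": ",
      length(toxLinked))

  # --- QSPR: GA triples per pathway ----------------------------------------
  qs <- config$qspr
  targets <- pathwayTargets(indexSet, study, qs$whichPc)
  targets <- targets[compounds, , drop = FALSE]
  populations <- clock("qspr_ga", {
    lapply(colnames(targets), function(pw)
      gaSearch(targets[, pw], descriptors, nRuns = qs$nRuns,
               population = qs$population, generations = qs$generations,
               mutationRate = qs$mutationRate, threshold = qs$threshold,
               testR2Min = qs$testR2Min, cvFolds = qs$cvFolds, split = qs$split,
               goalFitness = qs$goalFitness,
               seed = stageSeed(seed, paste0("qspr_", pw)),
               pathwayId = pw, pcIndex = qs$whichPc))
  })
  names(populations) <- colnames(targets)
  pcfLinked <- names(populations)[vapply(populations, isFlagged, logical(1))]
  writeModelPopulations(populations, file.path(outputDir, "qspr_models.json"))
  writeTsv(qsprSummary(populations, descriptors),
           file.path(outputDir, "qspr_summary.tsv"))
  net <- descriptorGroupNetwork(populations, descriptors)
  writeTsv(net$edges, file.path(outputDir, "descriptor_group_network.tsv"))
  say("PCF-linked pathways: ", length(pcfLinked))

  # --- pathway map + association ------------------------------------------
  sim <- clock("jaccard", jaccardMatrix(
    geneSetsObj,
    restrictToGenes = if (isTRUE(config$map$restrictToExpressed))
      rownames(exprsMatrix(study)) else NULL))
  mapClust <- clusterPathways(sim)
  assoc <- NULL
  if (length(pcfLinked) && length(toxLinked)) {
    assoc <- clock("association",
      associationTest(mapClust$hclust,
                      intersect(pcfLinked, mapClust$hclust$labels),
                      intersect(toxLinked, mapClust$hclust$labels),
                      nPerm = config$map$nPerm,
                      seed = stageSeed(seed, "association")))
    say("map association: p = ", signif(assoc@pValue, 3),
        " (cophenetic r = ", round(mapClust$copheneticR, 3), ")")
  }
  writePathwayMap(sim, mapClust, assoc, pcfLinked, toxLinked, outputDir)

  # --- classifier ----------------------------------------------------------
  cl <- config$classifier
  classifierOut <- NULL
  if (length(pcfLinked)) {
    split <- splitFeatures(descriptors, populations, cl$corCutoff)
    say("feature split: ", length(split@linked), " linked / ",
        length(split@uncorrelated), " uncorrelated")
    labels <- toxicityLabels(study)[compounds]
    runSearch <- function(subset, tag)
      gaClassifierSearch(descriptors, labels, subset,
                         chromosomeLen = cl$chromosomeLen, kFolds = cl$kFolds,
                         nRuns = cl$nRuns, population = cl$population,
                         generations = cl$generations,
                         mutationRate = cl$mutationRate, priors = cl$priors,
                         seed = stageSeed(seed, paste0("classifier_", tag)))
    searchLinked <- clock("classifier_linked", runSearch(split@linked, "linked"))
    searchUncor <- clock("classifier_uncorrelated",
                         runSearch(split@uncorrelated, "uncorrelated"))
    comparison <- compareSubsets(searchLinked$accuracies, searchUncor$accuracies)
    rep <- representativeModel(searchLinked, descriptors, labels,
                               kFolds = cl$kFolds,
                               seed = stageSeed(seed, "representative"))
    say("classifier accuracy (linked vs uncorrelated): ",
        round(100 * comparison$meanLinked, 1), "% vs ",
        round(100 * comparison$meanUncorrelated, 1), "%; representative ",
        "sensitivity ", round(rep$sensitivity, 3),
        ", specificity ", round(rep$specificity, 3))
    writeTsv(data.frame(subset = rep(c("linked", "uncorrelated"),
                                     c(length(searchLinked$accuracies),
                                       length(searchUncor$accuracies))),
                        accuracy = c(searchLinked$accuracies,
                                     searchUncor$accuracies)),
             file.path(outputDir, "accuracy_distributions.tsv"))
    jsonlite::write_json(
      list(linked = list(n = length(split@linked)),
           uncorrelated = list(n = length(split@uncorrelated)),
           mean_accuracy_linked = comparison$meanLinked,
           mean_accuracy_uncorrelated = comparison$meanUncorrelated,
           difference = comparison$difference, p_value = comparison$p.value),
      file.path(outputDir, "subset_comparison.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(features = rep$features, cv_accuracy = rep$cvAccuracy,
           sensitivity = rep$sensitivity, specificity = rep$specificity,
           confusion = as.list(rep$confusion)),
      file.path(outputDir, "representative_model.json"),
      auto_unbox = TRUE, digits = NA)
    writeTsv(rep$pcaCoords, file.path(outputDir, "representative_pca.tsv"),
             rowLabel = "compound")
    classifierOut <- list(split = split, linked = searchLinked,
                          uncorrelated = searchUncor,
                          comparison = comparison, representative = rep)
  }

  # --- manifest ------------------------------------------------------------
  outFiles <- sort(setdiff(list.files(outputDir, recursive = TRUE),
                           "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(outputDir, outFiles)))
  names(checksums) <- outFiles
  manifest <- list(
    package = "pcflink",
    version = as.character(utils::packageVersion("pcflink")),
    seed = seed,
    config = unclass(config),
    stage_seconds = timings,
    outputs = outFiles,
    checksums = checksums,
    counts = list(
      retained_pathways = length(retainedPathways(indexSet)),
      differential_pathways = length(toxLinked),
      pcf_linked_pathways = length(pcfLinked),
      linked_features = if (!is.null(classifierOut))
        length(classifierOut$split@linked) else 0L,
      uncorrelated_features = if (!is.null(classifierOut))
        length(classifierOut$split@uncorrelated) else 0L))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, study = study, geneSets = geneSetsObj,
                 descriptors = descriptors, truth = truth,
                 indexSet = indexSet, perturbation = pert,
                 drugClustering = drugClust, differential = diffRes,
                 populations = populations, pcfLinked = pcfLinked,
                 similarity = sim, mapClustering = mapClust,
                 association = assoc, classifier = classifierOut,
                 outputDir = outputDir))
}
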