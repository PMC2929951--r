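# Readers and writers for the on-disk artifacts: GMT gene sets, TSV expression
# and metadata, TSV descriptors, YAML configuration. All delimited files are
# tab-separated with a header row; numerics are written at full double
# precision so a write/read round trip is the identity.

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as
#' \code{id <tab> description <tab> member1 <tab> member2 ...}. The description
#' column is used as the set's category label. Duplicate members within a set
#' are collapsed.
#'
#' @param path path to a GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene sets in '", path, "'")
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  cats <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d in '%s': expected id, description and >= 1 member",
                   i, path))
    ids[i] <- f[1]
    cats[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- ids
  GeneSetCollection(sets, category = cats)
}

#' Write a gene-set collection to a GMT file
#'
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(geneSets, path) {
  sets <- geneSets(geneSets)
  cats <- setCategories(geneSets)
  lines <- vapply(names(sets), function(id)
    paste(c(id, cats[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression study from TSV matrix + metadata files
#'
#' The matrix file has gene ids in the first column (\code{gene_id}) and one
#' column per sample. The metadata file has columns \code{sample_id},
#' \code{compound_id}, \code{role}, \code{match_group}, \code{toxicity} and
#' must cover every sample in the matrix. Missing expression values are an
#' error: the matrix is assumed already pre-processed.
#'
#' @param path expression matrix TSV.
#' @param metaPath sample metadata TSV.
#' @return A validated \linkS4class{ExpressionStudy}.
#' @export
readExpressionStudy <- function(path, metaPath) {
  tab <- readTsv(path)
  if (colnames(tab)[1] != "gene_id")
    stop("expression matrix must have 'gene_id' as its first column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  meta <- readTsv(metaPath)
  ExpressionStudy(m, meta)
}

#' Write an expression study to TSV matrix + metadata files
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param path expression matrix TSV output path.
#' @param metaPath metadata TSV output path.
#' @return the matrix path, invisibly.
#' @export
writeExpressionStudy <- function(study, path, metaPath) {
  writeTsv(exprsMatrix(study), path, rowLabel = "gene_id")
  meta <- sampleMeta(study)
  writeTsv(meta, metaPath, rowLabel = "sample_id")
  invisible(path)
}

#' Read a descriptor matrix from TSV value + group files
#'
#' The value file has compound ids in the first column (\code{compound_id}) and
#' one column per descriptor. The group file has columns \code{descriptor_id}
#' and \code{group}. Descriptors containing any missing value are dropped (only
#' features computable for all compounds are kept) and the dropped count is
#' reported with a message and the \code{"dropped"} attribute.
#'
#' @param path descriptor value TSV.
#' @param groupsPath descriptor-group annotation TSV.
#' @return A \linkS4class{DescriptorMatrix} with attribute \code{dropped}.
#' @export
readDescriptorMatrix <- function(path, groupsPath) {
  tab <- readTsv(path)
  if (colnames(tab)[1] != "compound_id")
    stop("descriptor matrix must have 'compound_id' as its first column")
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab$compound_id
  storage.mode(v) <- "double"
  keep <- colSums(is.na(v)) == 0L
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(sprintf("dropped %d descriptor(s) with missing values", nDropped))
  v <- v[, keep, drop = FALSE]
  if (ncol(v) == 0L) stop("no complete descriptors remain")
  g <- readTsv(groupsPath)
  if (!all(c("descriptor_id", "group") %in% colnames(g)))
    stop("group file needs columns 'descriptor_id' and 'group'")
  groups <- stats::setNames(g$group, g$descriptor_id)
  missing <- setdiff(colnames(v), names(groups))
  if (length(missing))
    stop("descriptors without a group label: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- DescriptorMatrix(v, groups[colnames(v)])
  attr(out, "dropped") <- nDropped
  out
}

#' Write a descriptor matrix to TSV value + group files
#'
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @param path descriptor value TSV output path.
#' @param groupsPath group annotation TSV output path.
#' @return the value path, invisibly.
#' @export
writeDescriptorMatrix <- function(descriptors, path, groupsPath) {
  writeTsv(descriptorValues(descriptors), path, rowLabel = "compound_id")
  g <- descriptorGroups(descriptors)
  writeTsv(data.frame(descriptor_id = names(g), group = unname(g),
                      stringsAsFactors = FALSE), groupsPath)
  invisible(path)
}

#' Check that expression and descriptor compound panels agree
#'
#' Compound identifiers are the join key between the expression study and the
#' descriptor matrix; a mismatch is fatal rather than silently dropped.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param descriptors a \linkS4class{DescriptorMatrix}.
#' @return the common compound ids, in study order.
#' @export
matchCompounds <- function(study, descriptors) {
  sc <- compoundIds(study)
  dc <- rownames(descriptorValues(descriptors))
  if (!all(sc %in% dc))
    stop("compounds present in the expression study but absent from the descriptor matrix: ",
         paste(utils::head(setdiff(sc, dc), 5), collapse = ", "))
  sc
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to \code{\link{defaultConfig}}; thresholds are
#' range-checked.
#'
#' @param path YAML file.
#' @return a validated config list (class \code{pcflink_config}).
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultConfig(), user)
  validateConfig(cfg)
}

#' Write a pipeline configuration to YAML
#' @param config a config list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
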