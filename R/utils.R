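# Internal helpers: reproducible RNG scoping and derived stage seeds.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global \code{.Random.seed}, so seeded operations do
#' not perturb the caller's random stream. All stochastic operations in the
#' package route through this helper, which is what makes outputs byte-identical
#' under a fixed seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a base seed
#'
#' A small deterministic hash of the stage name is folded into the base seed so
#' that pipeline stages draw from independent, individually reproducible
#' substreams. The result always lies in [1, 2^31 - 2].
#'
#' @param seed base integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @keywords internal
stageSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483562 + 1)
}

# format numbers at full double precision for TSV round-trips
fmtFull <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

# write a data.frame / matrix as TSV with full-precision numerics
writeTsv <- function(x, path, rowLabel = NULL) {
  df <- as.data.frame(x, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(rowLabel)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE), rowLabel),
                df)
    rownames(df) <- NULL
  }
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmtFull(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

# stratified / plain fold assignment, deterministic given the current RNG state
makeFolds <- function(n, k, strata = NULL) {
  if (is.null(strata)) {
    fold <- integer(n)
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
    fold
  } else {
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
}
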