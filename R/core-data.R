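# Readers/writers for the three tables, dataset splitting, CV folds.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

logMsg <- function(...) message("[LatentMicrobiome] ", sprintf(...))

.readTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Load a taxa-abundance count table from TSV
#'
#' Native on-disk orientation is taxa as rows and samples as columns (the
#' common QIIME/biom TSV export); set \code{orientation = "samples"} when
#' the file has samples as rows instead.
#'
#' @param path TSV file; header row, first column identifiers, numeric body.
#' @param orientation \code{"taxa"} (rows are taxa, default) or
#'   \code{"samples"}.
#' @return An \linkS4class{AbundanceTable} on the \code{counts} scale.
#' @export
loadAbundanceTable <- function(path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  df <- .readTsv(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifier in ", basename(path), ": ",
         ids[duplicated(ids)][1L])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad, colnames(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  AbundanceTable(m, scale = "counts")
}

#' Write an AbundanceTable to TSV (taxa as rows)
#'
#' Values are written with full double precision so a write/load
#' round-trip is exact.
#'
#' @param table an \linkS4class{AbundanceTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(table, path) {
  v <- abundanceValues(table)
  df <- data.frame(taxon_id = rownames(v),
                   apply(v, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("taxon_id", colnames(v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a taxonomy table from TSV
#'
#' Expects a first column of taxon ids and the seven rank columns
#' (Kingdom..Species); missing entries become \code{"unclassified"}.
#'
#' @param path TSV file.
#' @return A \linkS4class{TaxonomyTable}.
#' @export
loadTaxonomyTable <- function(path) {
  df <- .readTsv(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate taxon id in taxonomy: ", ids[duplicated(ids)][1L])
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  TaxonomyTable(df)
}

#' @rdname loadTaxonomyTable
#' @param taxonomy a \linkS4class{TaxonomyTable} to write.
#' @export
writeTaxonomyTable <- function(taxonomy, path) {
  df <- lineage(taxonomy)
  out <- cbind(taxon_id = rownames(df), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load per-sample environmental metadata from TSV
#'
#' First column sample ids; remaining columns features. Rows containing
#' missing values (NA or empty cells) are dropped and the count logged,
#' mirroring standard metadata curation for this kind of study.
#'
#' @param path TSV file.
#' @param kinds optional named character vector forcing feature kinds.
#' @param units optional named character vector of units.
#' @return An \linkS4class{EnvironmentTable}.
#' @export
loadEnvironmentTable <- function(path, kinds = NULL, units = character()) {
  df <- .readTsv(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id in metadata: ", ids[duplicated(ids)][1L])
  df <- df[, -1L, drop = FALSE]
  df[df == ""] <- NA
  keep <- stats::complete.cases(df)
  if (any(!keep))
    logMsg("dropped %d metadata rows with missing values", sum(!keep))
  df <- df[keep, , drop = FALSE]
  rownames(df) <- ids[keep]
  EnvironmentTable(df, kinds = kinds, units = units)
}

#' @rdname loadEnvironmentTable
#' @param env an \linkS4class{EnvironmentTable} to write.
#' @export
writeEnvironmentTable <- function(env, path) {
  df <- environmentData(env)
  out <- cbind(sample_id = rownames(df), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM-format OTU table
#'
#' Thin wrapper over the Bioconductor \pkg{biomformat} reader, converting
#' to the package's internal \linkS4class{AbundanceTable}.
#'
#' @param path a BIOM file.
#' @return An \linkS4class{AbundanceTable} on the \code{counts} scale.
#' @export
loadBiomTable <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("package 'biomformat' is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  AbundanceTable(m, scale = "counts")
}

#' Split samples into train/test with cross-validation folds
#'
#' A uniform random permutation under an explicit seed assigns
#' \code{round(testFraction * n)} samples to the test set; the remaining
#' training samples are dealt round-robin into \code{k} validation folds
#' whose sizes differ by at most one. The same seed always reproduces the
#' same split. No stratification is applied.
#'
#' @param sampleIds character vector of sample ids.
#' @param testFraction fraction in (0, 1) held out for testing.
#' @param k number of cross-validation folds (>= 2).
#' @param seed integer seed.
#' @return A \linkS4class{SplitIndices}.
#' @examples
#' sp <- splitDataset(paste0("s", 1:100), 0.1, k = 5, seed = 1)
#' length(testIds(sp))  # 10
#' @export
splitDataset <- function(sampleIds, testFraction = 0.1, k = 5L, seed = 1L) {
  n <- length(sampleIds)
  stopifnot(testFraction > 0, testFraction < 1, k >= 2)
  nTest <- round(testFraction * n)
  nTrain <- n - nTest
  if (k > nTrain)
    stop(sprintf("k = %d folds exceed the %d training samples", k, nTrain))
  withSeed(seed, {
    perm <- sample(sampleIds)
    test <- perm[seq_len(nTest)]
    train <- perm[nTest + seq_len(nTrain)]
    foldOf <- rep_len(seq_len(k), nTrain)
    folds <- lapply(seq_len(k), function(f)
      list(fit = train[foldOf != f], val = train[foldOf == f]))
    new("SplitIndices", trainIds = train, testIds = test,
        cvFolds = folds, seed = as.integer(seed))
  })
}
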