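# Training losses and evaluation metrics: Bray-Curtis, mean Pearson,
# MAE/MSE/MAPE, per-OTU RRSE, best-predicted ranking.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{sum(|u - v|) / sum(u + v)}; for two relative-abundance vectors
#' each summing to one this reduces to \code{sum(|u - v|) / 2}. Bounded
#' in [0, 1] for nonnegative input; symmetric; not a metric (no triangle
#' inequality is asserted).
#'
#' @param u,v nonnegative numeric vectors of equal length, not both zero.
#' @return a scalar in [0, 1].
#' @examples
#' brayCurtis(c(0.7, 0.3), c(0.5, 0.5))  # 0.2
#' @export
brayCurtis <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0))
    stop("Bray-Curtis requires nonnegative abundances")
  s <- sum(u) + sum(v)
  if (s == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(u - v)) / s
}

# Fast row-wise Pearson between two matrices; returns NA for constant rows.
.rowwisePearson <- function(a, b) {
  a <- a - rowMeans(a); b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a * a) * rowSums(b * b))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Mean Pearson correlation between predicted and actual compositions
#'
#' Correlates each sample's predicted vs actual composition across taxa
#' (\code{per_sample}, the default) or each taxon's predicted vs actual
#' abundance across samples (\code{per_otu}), then averages. Pairs where
#' either vector is constant carry no correlation and are excluded with a
#' count; if every pair is excluded the quantity is undefined and an
#' error is raised (notably: a mean predictor is constant per taxon, so
#' its per-OTU correlation does not exist, while its per-sample
#' correlation is finite).
#'
#' @param pred,actual taxa x samples matrices of equal shape.
#' @param orientation \code{"per_sample"} or \code{"per_otu"}.
#' @return scalar mean correlation, with attribute \code{n_excluded}.
#' @export
meanPearson <- function(pred, actual,
                        orientation = c("per_sample", "per_otu")) {
  orientation <- match.arg(orientation)
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  stopifnot(all(dim(pred) == dim(actual)))
  if (orientation == "per_sample") {
    stopifnot(nrow(pred) >= 2)
    r <- .rowwisePearson(t(pred), t(actual))
  } else {
    stopifnot(ncol(pred) >= 2)
    r <- .rowwisePearson(pred, actual)
  }
  excl <- sum(is.na(r))
  if (excl == length(r))
    stop("mean Pearson undefined: every ", sub("_", " ", orientation),
         " vector pair is constant")
  structure(mean(r, na.rm = TRUE), n_excluded = as.integer(excl))
}

#' Element-wise error metrics (MAE, MSE, MAPE)
#'
#' MAPE averages \code{|pred - actual| / actual} only over entries with
#' positive actual value (zeros dominate sparse microbiome matrices and
#' would make the ratio undefined); the number of entries used is
#' returned. MAPE is a fraction (0.1 = 10\%).
#'
#' @param pred,actual numeric matrices/vectors of equal shape.
#' @return list with \code{mae}, \code{mse}, \code{mape}, \code{mape_n}.
#' @export
errorMetrics <- function(pred, actual) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  stopifnot(all(dim(pred) == dim(actual)))
  d <- pred - actual
  pos <- actual > 0
  list(mae = mean(abs(d)), mse = mean(d^2),
       mape = if (any(pos)) mean(abs(d[pos]) / actual[pos]) else NA_real_,
       mape_n = as.integer(sum(pos)))
}

#' Per-taxon root relative squared error (RRSE)
#'
#' For taxon j, \code{sqrt(sum_s (pred - actual)^2 / sum_s (actual -
#' mean(actual_j))^2)} over the evaluation samples: the error relative to
#' always predicting the taxon's mean. 1.0 means no better than the mean
#' predictor. Scale-independent, so taxa with very different abundance
#' ranges are comparable. Zero-variance taxa are excluded and reported.
#'
#' @param pred,actual taxa x samples matrices, >= 2 samples.
#' @param referenceMean optional named vector of per-taxon means to use
#'   in the denominator (e.g. training-set means); defaults to the
#'   evaluation-set means.
#' @return named numeric vector of RRSE per taxon, with attribute
#'   \code{excluded} listing zero-variance taxa.
#' @export
rrsePerOtu <- function(pred, actual, referenceMean = NULL) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  stopifnot(all(dim(pred) == dim(actual)), ncol(actual) >= 2)
  mu <- if (is.null(referenceMean)) rowMeans(actual)
        else referenceMean[rownames(actual)]
  num <- rowSums((pred - actual)^2)
  den <- rowSums((actual - mu)^2)
  keep <- den > 0
  out <- sqrt(num[keep] / den[keep])
  names(out) <- rownames(actual)[keep]
  structure(out, excluded = rownames(actual)[!keep])
}

#' Rank best-predicted taxa by ascending RRSE
#'
#' Sorts taxa by ascending RRSE (ties broken by taxon id, so output is
#' deterministic), keeps the top \code{ceiling(topFraction * n)}, and
#' reports the percentage breakdown of their Phylum labels.
#'
#' @param rrse named per-taxon RRSE vector (see \code{\link{rrsePerOtu}}).
#' @param taxonomy a \linkS4class{TaxonomyTable}.
#' @param topFraction fraction in (0, 1] of taxa to keep.
#' @return list with \code{taxa} (data.frame taxon_id, rrse, Phylum) and
#'   \code{phylum_percent} (named numeric, descending).
#' @export
rankBestPredicted <- function(rrse, taxonomy, topFraction = 0.05) {
  stopifnot(topFraction > 0, topFraction <= 1)
  ord <- order(rrse, names(rrse))
  k <- ceiling(topFraction * length(rrse))
  top <- names(rrse)[ord][seq_len(k)]
  phyla <- lineage(taxonomy)[top, "Phylum"]
  pct <- sort(100 * table(phyla) / k, decreasing = TRUE)
  list(taxa = data.frame(taxon_id = top, rrse = unname(rrse[top]),
                         Phylum = phyla, stringsAsFactors = FALSE),
       phylum_percent = setNames(as.numeric(pct), names(pct)))
}

# ---- differentiable training losses -----------------------------------

LOSS_EPS <- 1e-8

# value + gradient wrt pred for a samples x taxa batch
.lossAndGrad <- function(kind, pred, target) {
  n <- nrow(pred)
  switch(kind,
    mse = {
      d <- pred - target
      list(value = mean(d^2), grad = 2 * d / length(d))
    },
    crossentropy = {
      list(value = -mean(rowSums(target * log(pred + LOSS_EPS))),
           grad = -(target / (pred + LOSS_EPS)) / n)
    },
    braycurtis = {
      num <- rowSums(abs(pred - target))
      den <- rowSums(pred + target)
      g <- (sign(pred - target) * den - num) / den^2 / n
      list(value = mean(num / den), grad = g)
    },
    stop("unknown loss kind: ", kind))
}

#' Training loss value
#'
#' Batch-mean training losses: \code{mse} on any scale; \code{crossentropy}
#' (\code{-sum target * log(pred + 1e-8)}) and \code{braycurtis} require
#' simplex-valued predictions and are therefore only available on the TSS
#' pathway with a simplex output head — requesting them under CLR
#' normalization is a configuration error.
#'
#' @param kind \code{"mse"}, \code{"crossentropy"} or \code{"braycurtis"}.
#' @param pred,target samples x taxa matrices.
#' @return scalar loss.
#' @export
lossValue <- function(kind, pred, target) {
  kind <- match.arg(kind, c("mse", "crossentropy", "braycurtis"))
  .lossAndGrad(kind, as.matrix(pred), as.matrix(target))$value
}

#' Evaluate predicted against actual compositions
#'
#' Computes the full metric panel on the relative-abundance scale: mean
#' Pearson (chosen orientation), mean per-sample Bray-Curtis, MAE, MSE,
#' MAPE and per-taxon RRSE.
#'
#' @param pred,actual \linkS4class{AbundanceTable}s on the \code{tss}
#'   scale with matching taxa and samples.
#' @param orientation Pearson orientation (see \code{\link{meanPearson}}).
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateComposition <- function(pred, actual,
                                orientation = c("per_sample", "per_otu")) {
  orientation <- match.arg(orientation)
  stopifnot(is(pred, "AbundanceTable"), is(actual, "AbundanceTable"))
  if (abundanceScale(pred) != "tss" || abundanceScale(actual) != "tss")
    stop("evaluation happens on the tss scale; map outputs through ",
         "inverseToRelative first")
  p <- abundanceValues(pred)[taxonIds(actual), sampleIds(actual),
                             drop = FALSE]
  a <- abundanceValues(actual)
  r <- meanPearson(p, a, orientation)
  bc <- mean(vapply(seq_len(ncol(a)),
                    function(j) brayCurtis(p[, j], a[, j]), numeric(1)))
  em <- errorMetrics(p, a)
  rr <- if (ncol(a) >= 2) rrsePerOtu(p, a) else
    structure(numeric(), excluded = character())
  new("EvaluationReport",
      pearsonMean = as.numeric(r), orientation = orientation,
      brayCurtisMean = bc, mae = em$mae, mse = em$mse,
      mape = em$mape, mapeN = em$mape_n,
      pearsonExcluded = attr(r, "n_excluded"),
      perOtuRrse = as.numeric(rr) |> setNames(names(rr)),
      rrseExcluded = attr(rr, "excluded"),
      nSamples = ncol(a), nTaxa = nrow(a))
}

#' Write an evaluation report to TSV/JSON
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output path; extension \code{.json} writes JSON, anything
#'   else a two-column TSV of summary metrics (per-taxon RRSE goes to a
#'   sibling \code{*_rrse.tsv}).
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  x <- list(pearson_mean = report@pearsonMean,
            orientation = report@orientation,
            braycurtis_mean = report@brayCurtisMean,
            mae = report@mae, mse = report@mse, mape = report@mape,
            mape_n = report@mapeN, pearson_excluded = report@pearsonExcluded,
            n_samples = report@nSamples, n_taxa = report@nTaxa)
  if (grepl("\\.json$", path)) {
    x$per_otu_rrse <- as.list(report@perOtuRrse)
    x$rrse_excluded <- report@rrseExcluded
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(metric = names(x),
                     value = vapply(x, as.character, character(1)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(report@perOtuRrse)) {
      rp <- sub("(\\.[^.]+)?$", "_rrse.tsv", path)
      write.table(data.frame(taxon_id = names(report@perOtuRrse),
                             rrse = report@perOtuRrse),
                  rp, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
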