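#' @import methods
#' @importFrom stats cor rmultinom runif rnorm sd setNames predict
#' @importFrom utils read.delim write.table head modifyList
NULL

TAXONOMIC_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family",
                     "Genus", "Species")

#' Taxa-by-samples abundance matrix
#'
#' Central container for microbial community data: a numeric matrix with
#' taxa as rows and samples as columns, tagged with the scale its values
#' live on. Raw sequencing output is on the \code{counts} scale;
#' \code{\link{tssNormalize}} maps it to per-sample relative abundances
#' (\code{tss}, columns sum to 1) and \code{\link{clrTransform}} to
#' centered log-ratio coordinates (\code{clr}, columns sum to 0).
#'
#' @slot values numeric matrix, taxa x samples, with unique dimnames.
#' @slot scale one of \code{"counts"}, \code{"tss"}, \code{"clr"}.
#' @export
setClass("AbundanceTable",
         representation(values = "matrix", scale = "character"))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msgs <- c(msgs, "values must have taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, sprintf("duplicate taxon id: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
  if (anyDuplicated(colnames(v)))
    msgs <- c(msgs, sprintf("duplicate sample id: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  if (length(object@scale) != 1L ||
      !object@scale %in% c("counts", "tss", "clr"))
    msgs <- c(msgs, "scale must be one of counts, tss, clr")
  else {
    if (object@scale %in% c("counts", "tss") && any(v < 0))
      msgs <- c(msgs, "negative abundance not allowed on counts/tss scale")
    if (object@scale == "tss" && ncol(v) > 0 &&
        any(abs(colSums(v) - 1) > 1e-9))
      msgs <- c(msgs, "tss columns must sum to 1 (tol 1e-9)")
    if (object@scale == "clr" && ncol(v) > 0 &&
        any(abs(colSums(v)) > 1e-9))
      msgs <- c(msgs, "clr columns must sum to 0 (tol 1e-9)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric taxa x samples matrix with dimnames.
#' @param scale character scale tag; default \code{"counts"}.
#' @return An \linkS4class{AbundanceTable}.
#' @examples
#' m <- matrix(c(3, 2, 5, 0, 5, 5), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(values, scale = "counts") {
  new("AbundanceTable", values = as.matrix(values), scale = scale)
}

#' Per-taxon taxonomic lineages
#'
#' One row per taxon covering the seven standard ranks Kingdom..Species.
#' Ranks that could not be assigned are recorded with an explicit
#' \code{"unclassified"} marker rather than NA.
#'
#' @slot lineage data.frame with rownames = taxon ids and the seven rank
#'   columns, all character.
#' @export
setClass("TaxonomyTable", representation(lineage = "data.frame"))

setValidity("TaxonomyTable", function(object) {
  df <- object@lineage
  msgs <- character()
  if (!all(TAXONOMIC_RANKS %in% colnames(df)))
    msgs <- c(msgs, paste("lineage must contain columns",
                          paste(TAXONOMIC_RANKS, collapse = ", ")))
  if (anyDuplicated(rownames(df)))
    msgs <- c(msgs, "duplicate taxon id in taxonomy")
  if (any(vapply(df[intersect(TAXONOMIC_RANKS, colnames(df))],
                 function(x) !is.character(x), logical(1))))
    msgs <- c(msgs, "rank columns must be character")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxonomyTable
#' @param lineage data.frame of rank columns, rownames = taxon ids.
#' @return A \linkS4class{TaxonomyTable}.
#' @export
TaxonomyTable <- function(lineage) {
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  for (r in intersect(TAXONOMIC_RANKS, colnames(lineage)))
    lineage[[r]] <- as.character(lineage[[r]])
  lineage[is.na(lineage)] <- "unclassified"
  new("TaxonomyTable", lineage = lineage)
}

#' Per-sample environmental metadata
#'
#' Mixed numeric/categorical feature values per sample, plus a schema
#' declaring each feature's kind and (for numeric features) its units.
#' Rows with missing values are dropped at load time with a logged count.
#'
#' @slot data data.frame, rownames = sample ids.
#' @slot kinds named character vector, \code{"numeric"} or
#'   \code{"categorical"} per feature.
#' @slot units named character vector of units for numeric features.
#' @export
setClass("EnvironmentTable",
         representation(data = "data.frame", kinds = "character",
                        units = "character"))

setValidity("EnvironmentTable", function(object) {
  msgs <- character()
  if (anyDuplicated(rownames(object@data)))
    msgs <- c(msgs, "duplicate sample id in metadata")
  if (!all(colnames(object@data) %in% names(object@kinds)))
    msgs <- c(msgs, "every feature needs a declared kind")
  if (any(!object@kinds %in% c("numeric", "categorical")))
    msgs <- c(msgs, "kinds must be numeric or categorical")
  if (anyNA(object@data))
    msgs <- c(msgs, "missing values must be dropped before construction")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnvironmentTable
#'
#' Feature kinds default to the column classes: numeric columns become
#' numeric features, everything else categorical.
#'
#' @param data data.frame with rownames = sample ids.
#' @param kinds optional named character vector overriding inference.
#' @param units optional named character vector of units.
#' @return An \linkS4class{EnvironmentTable}.
#' @export
EnvironmentTable <- function(data, kinds = NULL, units = character()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(kinds)) {
    kinds <- vapply(data, function(x)
      if (is.numeric(x)) "numeric" else "categorical", character(1))
  }
  for (f in names(kinds)[kinds == "categorical"])
    data[[f]] <- as.character(data[[f]])
  new("EnvironmentTable", data = data, kinds = kinds, units = units)
}

#' Train/test split with cross-validation folds
#'
#' @slot trainIds,testIds disjoint character vectors of sample ids.
#' @slot cvFolds list of \code{list(fit, val)} id pairs partitioning the
#'   training ids.
#' @slot seed integer seed the split was drawn under.
#' @export
setClass("SplitIndices",
         representation(trainIds = "character", testIds = "character",
                        cvFolds = "list", seed = "integer"))

setValidity("SplitIndices", function(object) {
  msgs <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msgs <- c(msgs, "train and test ids overlap")
  vals <- unlist(lapply(object@cvFolds, `[[`, "val"))
  if (anyDuplicated(vals))
    msgs <- c(msgs, "validation folds overlap")
  if (length(vals) && !setequal(vals, object@trainIds))
    msgs <- c(msgs, "folds must partition the training ids")
  if (length(msgs)) msgs else TRUE
})

#' Fitted environmental-feature encoding
#'
#' Learned on training samples only: numeric features are z-scored with
#' the training mean and population standard deviation; categorical
#' features are one-hot encoded against the training vocabulary (unseen
#' categories map to an all-zero block). Training min/max are kept so
#' scenario prediction can flag extrapolation.
#'
#' @slot features feature names in declaration order.
#' @slot kinds named character vector per feature.
#' @slot centers,scales,mins,maxs named numeric vectors (numeric features).
#' @slot levels named list of sorted category vocabularies.
#' @slot units named character vector.
#' @export
setClass("EncodingSchema",
         representation(features = "character", kinds = "character",
                        centers = "numeric", scales = "numeric",
                        mins = "numeric", maxs = "numeric",
                        levels = "list", units = "character"))

setClassUnion("EncodingSchemaOrNULL", c("EncodingSchema", "NULL"))

#' Normalization state stored inside trained models
#'
#' Records which compositional normalization a model was trained under
#' (\code{tss} or \code{tss_clr}) and the pseudocount added to counts
#' before TSS on the CLR pathway, so that model outputs can always be
#' mapped back to relative abundances.
#'
#' @slot method \code{"tss"} or \code{"tss_clr"}.
#' @slot pseudocount positive number (CLR pathway only).
#' @export
setClass("NormalizationState",
         representation(method = "character", pseudocount = "numeric"))

setValidity("NormalizationState", function(object) {
  if (!object@method %in% c("tss", "tss_clr"))
    return("method must be tss or tss_clr")
  if (object@method == "tss_clr" && object@pseudocount <= 0)
    return("pseudocount must be positive for tss_clr")
  TRUE
})

#' @rdname NormalizationState-class
#' @param method normalization method.
#' @param pseudocount pseudocount for the CLR pathway.
#' @export
NormalizationState <- function(method = "tss", pseudocount = 1) {
  new("NormalizationState", method = method, pseudocount = pseudocount)
}

#' Trained autoencoder bundle
#'
#' Holds the OTU encoder, the optional environmental encoder, the shared
#' decoder, the architecture configuration, the normalization state, the
#' fitted feature-encoding schema (when an environmental encoder is
#' present) and the per-epoch training history.
#'
#' @slot otuEncoder,envEncoder,decoder internal network parameter lists.
#' @slot config the \code{\link{architectureConfig}} list used.
#' @slot normalization \linkS4class{NormalizationState}.
#' @slot schema \linkS4class{EncodingSchema} or NULL.
#' @slot history data.frame of per-epoch train/validation losses.
#' @slot taxonIds taxa the decoder emits, in output order.
#' @export
setClass("TrainedAE",
         representation(otuEncoder = "list", envEncoder = "list",
                        decoder = "list", config = "list",
                        normalization = "NormalizationState",
                        schema = "EncodingSchemaOrNULL",
                        history = "data.frame", taxonIds = "character"))

#' Deployable environment-to-composition prediction model
#'
#' An environment-to-latent predictor composed with a (frozen) decoder;
#' the artifact used for prediction, scenario analysis and transfer.
#'
#' @slot predictor internal network parameter list (env -> latent).
#' @slot decoder internal network parameter list (latent -> taxa).
#' @slot mode \code{"otu_latent"} or \code{"combined"}.
#' @slot schema \linkS4class{EncodingSchema} for the input features.
#' @slot normalization \linkS4class{NormalizationState}.
#' @slot features feature subset the predictor consumes.
#' @slot frozen logical, decoder weights frozen (always TRUE here).
#' @slot taxonIds decoder output taxa.
#' @export
setClass("PredictionModel",
         representation(predictor = "list", decoder = "list",
                        mode = "character", schema = "EncodingSchema",
                        normalization = "NormalizationState",
                        features = "character", frozen = "logical",
                        taxonIds = "character"))

#' Baseline predictor (default mean / linear / MLP)
#'
#' @slot kind \code{"default"}, \code{"linear"} or \code{"mlp"}.
#' @slot fit fitted parameters (kind-specific list).
#' @slot schema \linkS4class{EncodingSchema} or NULL (default kind).
#' @slot normalization \linkS4class{NormalizationState}.
#' @slot taxonIds output taxa.
#' @export
setClass("BaselineModel",
         representation(kind = "character", fit = "list",
                        schema = "EncodingSchemaOrNULL",
                        normalization = "NormalizationState",
                        taxonIds = "character"))

#' Evaluation report for predicted vs actual compositions
#'
#' All quantities are computed on the relative-abundance (TSS) scale so
#' that models trained under different normalizations are comparable.
#'
#' @slot pearsonMean mean Pearson correlation (orientation recorded).
#' @slot orientation \code{"per_sample"} or \code{"per_otu"}.
#' @slot brayCurtisMean mean Bray-Curtis dissimilarity in [0, 1].
#' @slot mae,mse,mape element-wise error metrics (mape over positive
#'   actual entries only; fraction, not percent).
#' @slot mapeN number of entries MAPE was computed over.
#' @slot pearsonExcluded number of constant vectors excluded.
#' @slot perOtuRrse named per-taxon root relative squared error.
#' @slot rrseExcluded ids of zero-variance taxa excluded from RRSE.
#' @slot nSamples,nTaxa evaluated shape.
#' @export
setClass("EvaluationReport",
         representation(pearsonMean = "numeric", orientation = "character",
                        brayCurtisMean = "numeric", mae = "numeric",
                        mse = "numeric", mape = "numeric", mapeN = "integer",
                        pearsonExcluded = "integer",
                        perOtuRrse = "numeric", rrseExcluded = "character",
                        nSamples = "integer", nTaxa = "integer"))
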