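#' @name accessors
#' @title Accessors for the core containers
#' @description Slot access for the S4 containers goes through these
#'   functions; slots are an implementation detail.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))
#' @rdname accessors
#' @export
setMethod("abundanceValues", "AbundanceTable", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))
#' @rdname accessors
#' @export
setMethod("abundanceScale", "AbundanceTable", function(x) x@scale)

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))
#' @rdname accessors
#' @export
setMethod("taxonIds", "AbundanceTable", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("taxonIds", "TaxonomyTable", function(x) rownames(x@lineage))
#' @rdname accessors
#' @export
setMethod("taxonIds", "PredictionModel", function(x) x@taxonIds)
#' @rdname accessors
#' @export
setMethod("taxonIds", "TrainedAE", function(x) x@taxonIds)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "EnvironmentTable", function(x) rownames(x@data))

#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname accessors
#' @export
setMethod("lineage", "TaxonomyTable", function(x) x@lineage)

#' @rdname accessors
#' @export
setGeneric("environmentData", function(x) standardGeneric("environmentData"))
#' @rdname accessors
#' @export
setMethod("environmentData", "EnvironmentTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))
#' @rdname accessors
#' @export
setMethod("featureKinds", "EnvironmentTable", function(x) x@kinds)
#' @rdname accessors
#' @export
setMethod("featureKinds", "EncodingSchema", function(x) x@kinds)

#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setMethod("trainIds", "SplitIndices", function(x) x@trainIds)

#' @rdname accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))
#' @rdname accessors
#' @export
setMethod("testIds", "SplitIndices", function(x) x@testIds)

#' @rdname accessors
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setMethod("cvFolds", "SplitIndices", function(x) x@cvFolds)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "TrainedAE", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("normalizationState",
           function(x) standardGeneric("normalizationState"))
#' @rdname accessors
#' @export
setMethod("normalizationState", "TrainedAE", function(x) x@normalization)
#' @rdname accessors
#' @export
setMethod("normalizationState", "PredictionModel",
          function(x) x@normalization)
#' @rdname accessors
#' @export
setMethod("normalizationState", "BaselineModel", function(x) x@normalization)

#' @rdname accessors
#' @export
setGeneric("perOtuRrse", function(x) standardGeneric("perOtuRrse"))
#' @rdname accessors
#' @export
setMethod("perOtuRrse", "EvaluationReport", function(x) x@perOtuRrse)

#' @rdname accessors
#' @export
setGeneric("pearsonMean", function(x) standardGeneric("pearsonMean"))
#' @rdname accessors
#' @export
setMethod("pearsonMean", "EvaluationReport", function(x) x@pearsonMean)

#' @rdname accessors
#' @export
setGeneric("brayCurtisMean", function(x) standardGeneric("brayCurtisMean"))
#' @rdname accessors
#' @export
setMethod("brayCurtisMean", "EvaluationReport", function(x) x@brayCurtisMean)

#' Subset an abundance table by taxa and/or samples
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param i taxa selector (ids or indices).
#' @param j samples selector (ids or indices).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @return An \linkS4class{AbundanceTable}. Subsetting taxa of a tss/clr
#'   table returns a \code{counts}-tagged view only when taxa are dropped
#'   from a closed scale would break closure; subsetting samples keeps the
#'   scale.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  keepScale <- x@scale
  if (!missing(i)) {
    v <- v[i, , drop = FALSE]
    if (keepScale != "counts" && nrow(v) != nrow(x@values))
      stop("cannot subset taxa on a closed (", keepScale,
           ") scale; subset counts and renormalize")
  }
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("AbundanceTable", values = v, scale = keepScale)
})

#' Subset an environment table by samples
#'
#' @param x an \linkS4class{EnvironmentTable}.
#' @param i sample selector (ids or indices).
#' @param j unused.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "EnvironmentTable", function(x, i, j, ..., drop = FALSE) {
  new("EnvironmentTable", data = x@data[i, , drop = FALSE],
      kinds = x@kinds, units = x@units)
})

#' @describeIn AbundanceTable-class dimensions (taxa, samples).
#' @param x object.
#' @export
setMethod("dim", "AbundanceTable", function(x) dim(x@values))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d taxa x %d samples [scale=%s]\n",
              nrow(object@values), ncol(object@values), object@scale))
  cat("  taxa:   ", paste(head(rownames(object@values), 3), collapse = ", "),
      if (nrow(object@values) > 3) ", ..." else "", "\n", sep = "")
  cat("  samples:", paste(head(colnames(object@values), 3), collapse = ", "),
      if (ncol(object@values) > 3) ", ..." else "", "\n", sep = "")
})

setMethod("show", "TaxonomyTable", function(object) {
  cat(sprintf("TaxonomyTable: %d taxa, ranks %s\n", nrow(object@lineage),
              paste(TAXONOMIC_RANKS, collapse = " > ")))
})

setMethod("show", "EnvironmentTable", function(object) {
  k <- object@kinds[colnames(object@data)]
  cat(sprintf("EnvironmentTable: %d samples x %d features (%d numeric, %d categorical)\n",
              nrow(object@data), ncol(object@data),
              sum(k == "numeric"), sum(k == "categorical")))
})

setMethod("show", "SplitIndices", function(object) {
  cat(sprintf("SplitIndices: %d train / %d test, %d CV folds (seed %d)\n",
              length(object@trainIds), length(object@testIds),
              length(object@cvFolds), object@seed))
})

setMethod("show", "TrainedAE", function(object) {
  cat(sprintf("TrainedAE: latent %d, %s loss, %s normalization, %s\n",
              object@config$latentDim, object@config$loss,
              object@normalization@method,
              if (length(object@envEncoder)) "combined (OTU+env encoders)"
              else "OTU encoder only"))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; best val loss %.6g\n",
                nrow(object@history), min(object@history$val_loss)))
})

setMethod("show", "PredictionModel", function(object) {
  cat(sprintf("PredictionModel [%s]: %s -> latent -> %d taxa (decoder %s)\n",
              object@mode, paste(object@features, collapse = ", "),
              length(object@taxonIds),
              if (object@frozen) "frozen" else "trainable"))
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel [%s]: %d output taxa\n", object@kind,
              length(object@taxonIds)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%d samples x %d taxa)\n",
              object@nSamples, object@nTaxa))
  cat(sprintf("  Pearson (%s): %.4f   Bray-Curtis: %.4f\n",
              object@orientation, object@pearsonMean,
              object@brayCurtisMean))
  cat(sprintf("  MAE %.3e  MSE %.3e  MAPE %.1f%% (over %d entries)\n",
              object@mae, object@mse, 100 * object@mape, object@mapeN))
  if (length(object@perOtuRrse))
    cat(sprintf("  per-OTU RRSE: median %.3f (%d taxa, %d excluded)\n",
                stats::median(object@perOtuRrse), length(object@perOtuRrse),
                length(object@rrseExcluded)))
})
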