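# Frozen-decoder transfer learning: reuse a trained decoder (and the
# latent geometry behind it) while fitting a new environment->latent
# predictor on a small dataset, whose features may differ entirely from
# the source's.

#' Transfer a trained latent space and decoder to a small dataset
#'
#' The knowledge transferred lives in the latent space and its decoder:
#' both stay frozen. The small dataset's compositions (they are
#' sequenced, just few) are pushed through the source OTU encoder to get
#' latent targets, a fresh \linkS4class{EncodingSchema} is fitted on the
#' small dataset's own features — which may be completely different from
#' the source's (e.g. soil pH/N/C instead of weather) — and a new
#' environment-to-latent predictor is trained against those targets. Taxa
#' must match the decoder's output exactly by id; to harmonize datasets
#' annotated at different depths, first aggregate both to a shared rank
#' with \code{\link{aggregateTaxa}} and train a source model at that rank.
#'
#' @param source a \linkS4class{TrainedAE} (the large-study model).
#' @param smallOtu counts-scale \linkS4class{AbundanceTable} of the small
#'   dataset; taxa must equal \code{taxonIds(source)}.
#' @param smallEnv paired \linkS4class{EnvironmentTable}.
#' @param cfg an \code{\link{architectureConfig}} for the predictor.
#' @param features optional feature subset of \code{smallEnv}.
#' @return A \linkS4class{PredictionModel} with the source's frozen
#'   decoder.
#' @export
transferFit <- function(source, smallOtu, smallEnv,
                        cfg = architectureConfig(), features = NULL) {
  stopifnot(is(source, "TrainedAE"))
  if (ncol(abundanceValues(smallOtu)) == 0L)
    stop("transfer requires at least one training sample")
  unmatched <- c(setdiff(taxonIds(smallOtu), taxonIds(source)),
                 setdiff(taxonIds(source), taxonIds(smallOtu)))
  if (length(unmatched))
    stop("taxa do not match the source decoder's output taxa: ",
         paste(head(unique(unmatched), 10), collapse = ", "),
         if (length(unique(unmatched)) > 10) ", ...",
         " (aggregate both datasets to a shared rank first)")
  smallOtu <- smallOtu[taxonIds(source), ]
  if (!identical(sampleIds(smallOtu), sampleIds(smallEnv)))
    stop("small dataset abundance and metadata samples do not match")
  z <- latentCodes(source, smallOtu)
  enc <- encodeEnvironment(smallEnv, features = features)
  pred <- trainLatentPredictor(enc$matrix, z, .predictorConfig(cfg))
  assemblePredictionModel(source, "otu_latent", predictor = pred,
                          schema = enc$schema)
}
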