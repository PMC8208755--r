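# Hypothetical-scenario prediction: predict compositions under modified
# environmental conditions (e.g. climate-change settings) and tabulate
# abundance shifts across conditions.

#' Predict compositions under hypothetical environmental conditions
#'
#' For each named condition, the listed feature values override the base
#' metadata for every sample, the model predicts the resulting
#' composition, and results are returned long-format with condition
#' labels. Typical conditions follow climate scenarios, e.g.
#' \code{list("hot and dry" = list(temperature = 86, rain = 0))} with
#' temperature in deg F and precipitation in inches (units are whatever
#' the schema recorded). Values outside the training range are permitted
#' — near-boundary scenarios are the point of the exercise — but trigger
#' a logged extrapolation warning.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param baseEnv \linkS4class{EnvironmentTable} of base conditions.
#' @param overrides named list of conditions; each condition is a named
#'   list/vector of feature values. An empty override predicts the base
#'   conditions unchanged.
#' @param taxonomy optional \linkS4class{TaxonomyTable} for aggregation.
#' @param aggregateLevel optional rank (e.g. \code{"Class"}) to report at.
#' @return data.frame with columns \code{condition}, \code{sample_id},
#'   \code{taxon_id}, \code{abundance}.
#' @export
scenarioPredict <- function(model, baseEnv, overrides,
                            taxonomy = NULL, aggregateLevel = NULL) {
  stopifnot(is(model, "PredictionModel"), is(baseEnv, "EnvironmentTable"))
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("every condition needs a label")
  schema <- model@schema
  out <- vector("list", length(overrides))
  for (ci in seq_along(overrides)) {
    label <- names(overrides)[ci]
    ov <- overrides[[ci]]
    df <- environmentData(baseEnv)
    for (f in names(ov)) {
      if (!f %in% schema@features)
        stop("unknown feature in condition '", label, "': ", f)
      val <- ov[[f]]
      if (schema@kinds[[f]] == "numeric") {
        val <- as.numeric(val)
        if (val < schema@mins[[f]] || val > schema@maxs[[f]])
          logMsg("condition '%s': %s = %g extrapolates beyond the training range [%g, %g]",
                 label, f, val, schema@mins[[f]], schema@maxs[[f]])
      }
      df[[f]] <- val
    }
    envC <- new("EnvironmentTable", data = df, kinds = baseEnv@kinds,
                units = baseEnv@units)
    pred <- predictComposition(model, envC)
    if (!is.null(aggregateLevel)) {
      if (is.null(taxonomy))
        stop("aggregation requires a taxonomy table")
      pred <- aggregateTaxa(pred, taxonomy, aggregateLevel)
    }
    v <- abundanceValues(pred)
    out[[ci]] <- data.frame(
      condition = label,
      sample_id = rep(colnames(v), each = nrow(v)),
      taxon_id = rep(rownames(v), times = ncol(v)),
      abundance = as.vector(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mean predicted abundance per condition and taxon
#'
#' Convenience summary of a \code{\link{scenarioPredict}} table: averages
#' predicted abundances over samples within each condition.
#'
#' @param scenarioTable output of \code{\link{scenarioPredict}}.
#' @return data.frame \code{condition}, \code{taxon_id},
#'   \code{mean_abundance}.
#' @export
summarizeScenario <- function(scenarioTable) {
  agg <- stats::aggregate(abundance ~ condition + taxon_id,
                          data = scenarioTable, FUN = mean)
  names(agg)[names(agg) == "abundance"] <- "mean_abundance"
  agg[order(agg$condition, agg$taxon_id), ]
}
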