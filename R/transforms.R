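# Compositional normalizations (TSS, CLR) with inverses, environmental
# feature encoding, taxonomic aggregation.

#' Total-sum scaling (TSS)
#'
#' Divides each sample (column) by its total, mapping counts to relative
#' abundances on the simplex.
#'
#' @param table an \linkS4class{AbundanceTable} on the \code{counts} scale.
#' @return An \linkS4class{AbundanceTable} with \code{scale = "tss"}.
#' @export
tssNormalize <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceScale(table) != "counts")
    stop("tssNormalize expects a counts-scale table")
  v <- abundanceValues(table)
  tot <- colSums(v)
  if (any(tot <= 0))
    stop("zero-depth sample: ", colnames(v)[which(tot <= 0)[1L]])
  AbundanceTable(sweep(v, 2L, tot, "/"), scale = "tss")
}

# CLR of a column-stochastic proportion matrix (no pseudocount); the
# internal path used for round-trip identities on strictly positive input.
.clrOfProportions <- function(p) {
  lg <- log(p)
  sweep(lg, 2L, colMeans(lg), "-")
}

#' Centered log-ratio transform (TSS + CLR)
#'
#' Adds a pseudocount to the raw counts, applies TSS, then maps each
#' entry to \code{log(x / geometric mean of its sample)}. Columns of the
#' result sum to zero. The pseudocount (default 1) handles the zeros that
#' dominate sparse microbiome counts and is recorded in the model's
#' \linkS4class{NormalizationState}.
#'
#' @param table an \linkS4class{AbundanceTable} on the \code{counts} scale.
#' @param pseudocount positive number added to counts before TSS.
#' @return An \linkS4class{AbundanceTable} with \code{scale = "clr"}.
#' @export
clrTransform <- function(table, pseudocount = 1) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceScale(table) != "counts")
    stop("clrTransform expects a counts-scale table")
  stopifnot(pseudocount > 0)
  v <- abundanceValues(table) + pseudocount
  p <- sweep(v, 2L, colSums(v), "/")
  AbundanceTable(.clrOfProportions(p), scale = "clr")
}

#' Map model outputs back to relative abundances
#'
#' Model outputs live on the scale the model was trained on; evaluation
#' always happens on the relative-abundance scale. TSS-trained outputs
#' are clipped at zero and re-closed to sum one; CLR-trained outputs are
#' mapped through softmax (exp then closure), which inverts the CLR up to
#' its closure constant.
#'
#' @param matrix taxa x samples numeric matrix of model outputs.
#' @param state the model's \linkS4class{NormalizationState}.
#' @return An \linkS4class{AbundanceTable} with \code{scale = "tss"}.
#' @export
inverseToRelative <- function(matrix, state) {
  stopifnot(is(state, "NormalizationState"))
  m <- as.matrix(matrix)
  if (state@method == "tss") {
    m[m < 0] <- 0
    tot <- colSums(m)
    tot[tot == 0] <- 1  # degenerate all-zero output -> uniform zeros kept
    m <- sweep(m, 2L, tot, "/")
  } else {
    m <- sweep(m, 2L, apply(m, 2L, max), "-")  # stabilized softmax
    m <- exp(m)
    m <- sweep(m, 2L, colSums(m), "/")
  }
  AbundanceTable(m, scale = "tss")
}

.lineageKey <- function(taxonomy, level) {
  ranks <- TAXONOMIC_RANKS[seq_len(match(level, TAXONOMIC_RANKS))]
  df <- lineage(taxonomy)
  do.call(paste, c(df[ranks], sep = ";"))
}

#' Aggregate taxa to a higher taxonomic rank
#'
#' Rows sharing the same lineage prefix up to \code{level} are summed, so
#' each sample's total mass is conserved exactly. Not defined on the CLR
#' scale, where sums are not meaningful.
#'
#' @param table an \linkS4class{AbundanceTable} (\code{counts} or
#'   \code{tss}).
#' @param taxonomy a \linkS4class{TaxonomyTable} covering the table's taxa.
#' @param level target rank, one of Phylum..Genus (or any rank above
#'   Species).
#' @return An \linkS4class{AbundanceTable} whose rows are lineage groups
#'   (ids are the ;-joined lineage prefix).
#' @export
aggregateTaxa <- function(table, taxonomy, level) {
  stopifnot(is(table, "AbundanceTable"), is(taxonomy, "TaxonomyTable"))
  if (abundanceScale(table) == "clr")
    stop("cannot aggregate on the clr scale; aggregate counts or tss")
  level <- match.arg(level, TAXONOMIC_RANKS[-1L])
  ids <- taxonIds(table)
  missing <- setdiff(ids, taxonIds(taxonomy))
  if (length(missing))
    stop("taxa missing from taxonomy: ", paste(head(missing, 5),
                                               collapse = ", "))
  key <- .lineageKey(taxonomy, level)[match(ids, taxonIds(taxonomy))]
  groups <- sort(unique(key))
  v <- abundanceValues(table)
  out <- rowsum(v, group = key, reorder = TRUE)
  AbundanceTable(out[groups, , drop = FALSE], scale = abundanceScale(table))
}

#' Fit or apply the environmental-feature encoding
#'
#' Numeric features are z-scored using the training mean and population
#' (denominator n) standard deviation; categorical features are one-hot
#' encoded against the training vocabulary, sorted for a deterministic
#' column order. Categories unseen at transform time map to an all-zero
#' block with a logged warning; zero-variance numeric features encode as
#' constant zero with a warning.
#'
#' @param env an \linkS4class{EnvironmentTable}.
#' @param schema a fitted \linkS4class{EncodingSchema}, or NULL to fit on
#'   \code{env} (the training set).
#' @param features optional feature subset (declaration order preserved).
#' @return list with \code{matrix} (samples x encoded columns) and
#'   \code{schema}.
#' @export
encodeEnvironment <- function(env, schema = NULL, features = NULL) {
  stopifnot(is(env, "EnvironmentTable"))
  df <- environmentData(env)
  if (is.null(schema)) {
    feats <- if (is.null(features)) colnames(df) else features
    miss <- setdiff(feats, colnames(df))
    if (length(miss)) stop("unknown feature: ", paste(miss, collapse = ", "))
    kinds <- featureKinds(env)[feats]
    centers <- scales <- mins <- maxs <- numeric()
    levs <- list()
    for (f in feats) {
      if (kinds[[f]] == "numeric") {
        x <- df[[f]]
        centers[[f]] <- mean(x)
        s <- sqrt(mean((x - mean(x))^2))
        if (s == 0) {
          warning("zero-variance numeric feature '", f,
                  "' encoded as constant 0")
        }
        scales[[f]] <- s
        mins[[f]] <- min(x)
        maxs[[f]] <- max(x)
      } else {
        levs[[f]] <- sort(unique(as.character(df[[f]])))
      }
    }
    schema <- new("EncodingSchema", features = feats, kinds = kinds,
                  centers = centers, scales = scales, mins = mins,
                  maxs = maxs, levels = levs,
                  units = env@units[intersect(names(env@units), feats)])
  }
  miss <- setdiff(schema@features, colnames(df))
  if (length(miss)) stop("metadata lacks feature: ",
                         paste(miss, collapse = ", "))
  cols <- list()
  for (f in schema@features) {
    if (schema@kinds[[f]] == "numeric") {
      x <- as.numeric(df[[f]])
      s <- schema@scales[[f]]
      z <- if (s == 0) rep(0, length(x)) else (x - schema@centers[[f]]) / s
      cols[[f]] <- matrix(z, ncol = 1L, dimnames = list(NULL, f))
    } else {
      vocab <- schema@levels[[f]]
      x <- as.character(df[[f]])
      unseen <- setdiff(unique(x), vocab)
      if (length(unseen))
        warning("unseen categor", if (length(unseen) > 1) "ies" else "y",
                " in '", f, "': ", paste(unseen, collapse = ", "),
                " (encoded as all-zero)")
      oh <- matrix(0, nrow = length(x), ncol = length(vocab),
                   dimnames = list(NULL, paste(f, vocab, sep = "=")))
      hit <- match(x, vocab)
      ok <- !is.na(hit)
      oh[cbind(which(ok), hit[ok])] <- 1
      cols[[f]] <- oh
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(df)
  list(matrix = m, schema = schema)
}
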