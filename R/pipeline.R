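#' Extract feature genes by error-margin analysis
#'
#' The full extraction pipeline: (1) rank all genes by two-sample t-test
#' relevance; (2) reorder the dataset by the relevance list; (3) build
#' the leave-one-out error-margin curve W(i) for i = 1..fMax; (4) fit
#' continuity-constrained two-segment polynomials over candidate
#' breakpoints and take the estimation-error minimizer f0; (5) return the
#' f0 most relevant genes, reported in the ORIGINAL gene coordinates.
#'
#' The procedure is deterministic given the dataset and settings; the
#' relevance list is computed once and shared by every stage.
#'
#' @param ds a two-class [ExpressionDataset-class], n >= 3.
#' @param fMax maximum number of considered genes (default 100, capped at
#'   the gene count).
#' @param degree polynomial order of the segment model (default 2).
#' @param cost soft-margin penalty C (default 1).
#' @param tTestVariant relevance t-test variant, see [genePValue()].
#' @return list with elements:
#'   \describe{
#'     \item{`features`}{[FeatureSet-class] of the f0 selected genes;}
#'     \item{`relevance`}{the [RelevanceList-class];}
#'     \item{`curve`}{the [MarginCurve-class];}
#'     \item{`fit`}{the [SegmentedFit-class] at the critical point;}
#'     \item{`profile`}{data.frame of candidate breakpoints `f` and
#'       estimation errors `epsilon`.}
#'   }
#' @examples
#' sets <- generateSynthetic(seed = 1)
#' \donttest{
#' res <- extractFeatures(sets$train)
#' featureSize(res$features)
#' }
#' @export
extractFeatures <- function(ds, fMax = 100, degree = 2L, cost = 1,
                            tTestVariant = c("pooled", "welch")) {
  if (nrow(ds@values) < 3)
    stop("stage ranking: need at least 3 samples")
  fMax <- min(fMax, ncol(ds@values))
  rl <- withStage("ranking", buildRelevanceList(ds, match.arg(tTestVariant)))
  ordered <- withStage("reorder", reorderDataset(ds, rl))
  curve <- withStage("margin-curve", marginCurve(ordered, fMax, cost))
  cp <- withStage("critical-point", findCriticalPoint(curve, degree))
  sel <- geneOrder(rl)[seq_len(cp$f0)]
  fs <- new("FeatureSet", indices = as.integer(sel),
            geneIds = geneIds(ds)[sel])
  list(features = fs, relevance = rl, curve = curve, fit = cp$fit,
       profile = cp$profile)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' t-test filter baseline
#'
#' Selects every gene whose two-sided two-sample t-test p-value is
#' strictly below `cutoff`, in relevance order. This is the classical
#' p-value-threshold filter used as a baseline against the error-margin
#' criterion; it fixes the selection by a significance parameter rather
#' than by the margin-curve breakpoint.
#'
#' @param ds a two-class [ExpressionDataset-class].
#' @param cutoff p-value threshold (default 0.005); genes with
#'   `p < cutoff` are selected (strict inequality, so `cutoff = 0`
#'   selects nothing).
#' @param tTestVariant see [genePValue()].
#' @return A [FeatureSet-class] (possibly empty), indices in original
#'   gene coordinates ordered by ascending p-value.
#' @export
ttestFilter <- function(ds, cutoff = 0.005,
                        tTestVariant = c("pooled", "welch")) {
  rl <- buildRelevanceList(ds, match.arg(tTestVariant))
  ord <- geneOrder(rl)
  sel <- ord[genePValues(rl)[ord] < cutoff]
  new("FeatureSet", indices = as.integer(sel), geneIds = geneIds(ds)[sel])
}
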