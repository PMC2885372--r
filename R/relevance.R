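#' Two-sample t-test p-value for one gene
#'
#' Two-sided p-value comparing the expression of a gene between the two
#' classes. The default is the classical pooled-variance (equal-variance)
#' two-sample t-test; Welch's unequal-variance variant is available via
#' `variant = "welch"`.
#'
#' Degenerate inputs are resolved by convention rather than error: when
#' both groups are constant, p = 1 if the group means agree (no evidence
#' of difference) and p = 0 if they differ (perfect separation).
#'
#' @param a expression values of the negative-class samples (>= 2).
#' @param b expression values of the positive-class samples (>= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return p-value in [0, 1].
#' @examples
#' genePValue(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))
#' @export
genePValue <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("each class needs at least 2 samples for a t-test")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = (variant == "pooled"))$p.value
}

#' Build the gene relevance list
#'
#' Computes per-gene two-sided t-test p-values between the two classes
#' and orders genes by decreasing relevance r_i = 1 - p_i, i.e. by
#' ascending p-value, ties broken by ascending original gene index
#' (stable, deterministic across platforms). Any strictly decreasing
#' transform of p yields the same ordering; 1 - p is used so the score is
#' directly interpretable.
#'
#' @param ds an [ExpressionDataset-class] with both classes present,
#'   >= 2 samples each.
#' @param variant t-test variant, see [genePValue()].
#' @return A [RelevanceList-class].
#' @export
buildRelevanceList <- function(ds, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  y <- classLabels(ds)
  if (sum(y == -1) < 2 || sum(y == 1) < 2)
    stop("both classes must be present with at least 2 samples each")
  v <- ds@values
  p <- vapply(seq_len(ncol(v)), function(j)
    genePValue(v[y == -1, j], v[y == 1, j], variant), numeric(1))
  ord <- order(p, seq_along(p))
  new("RelevanceList", geneOrder = as.integer(ord), pvalues = p,
      relevance = 1 - p, geneIds = geneIds(ds))
}

#' Reorder a dataset by relevance
#'
#' Permutes gene columns so that column k holds the k-th most relevant
#' gene, with gene identifiers permuted in lockstep; labels and samples
#' are untouched.
#'
#' @param ds an [ExpressionDataset-class].
#' @param rl a [RelevanceList-class] built from a dataset with the same
#'   gene identifiers.
#' @return The reordered [ExpressionDataset-class].
#' @export
reorderDataset <- function(ds, rl) {
  if (!identical(geneIds(ds), rl@geneIds))
    stop("gene identifiers of the dataset and the relevance list differ")
  ds[, geneOrder(rl)]
}
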