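#' @rdname ExpressionDataset-class
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) {
  v <- x@values
  dimnames(v) <- list(x@sampleIds, x@geneIds)
  v
})

#' @rdname ExpressionDataset-class
#' @export
setMethod("classLabels", "ExpressionDataset", function(x) x@labels)

#' @rdname ExpressionDataset-class
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) x@geneIds)

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) x@sampleIds)

#' @rdname ExpressionDataset-class
#' @export
setMethod("dim", "ExpressionDataset", function(x) dim(x@values))

#' Subset an ExpressionDataset
#'
#' `ds[i, j]` keeps samples `i` and genes `j`, labels and identifiers in
#' lockstep.
#'
#' @param x an ExpressionDataset.
#' @param i sample (row) index.
#' @param j gene (column) index.
#' @param ... ignored.
#' @param drop ignored; the result is always an ExpressionDataset.
#' @export
setMethod("[", "ExpressionDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  new("ExpressionDataset",
      values = x@values[i, j, drop = FALSE],
      labels = x@labels[i],
      geneIds = x@geneIds[j],
      sampleIds = x@sampleIds[i])
})

#' @export
setMethod("show", "ExpressionDataset", function(object) {
  n <- nrow(object@values); d <- ncol(object@values)
  cat("ExpressionDataset:", n, "samples x", d, "genes\n")
  cat("  classes: ", sum(object@labels == -1), " negative (-1), ",
      sum(object@labels == 1), " positive (+1)\n", sep = "")
})

#' @rdname RelevanceList-class
#' @export
setMethod("geneOrder", "RelevanceList", function(x) x@geneOrder)

#' @rdname RelevanceList-class
#' @export
setMethod("genePValues", "RelevanceList", function(x) {
  stats::setNames(x@pvalues, x@geneIds)
})

#' @rdname RelevanceList-class
#' @export
setMethod("relevanceScores", "RelevanceList", function(x) {
  stats::setNames(x@relevance, x@geneIds)
})

#' @export
setMethod("show", "RelevanceList", function(object) {
  d <- length(object@pvalues)
  cat("RelevanceList over", d, "genes\n")
  top <- utils::head(object@geneOrder, 5)
  cat("  top ranks:", paste(object@geneIds[top], collapse = ", "),
      if (d > 5) "..." else "", "\n")
})

#' @rdname Hyperplane-class
#' @export
setMethod("marginWeights", "Hyperplane", function(x) x@weights)

#' @rdname Hyperplane-class
#' @export
setMethod("bias", "Hyperplane", function(x) x@bias)

#' @export
setMethod("show", "Hyperplane", function(object) {
  cat("Hyperplane in", length(object@weights), "dimensions; ||h|| =",
      format(sqrt(sum(object@weights^2)), digits = 4),
      "; bias =", format(object@bias, digits = 4), "\n")
})

#' @rdname MarginCurve-class
#' @export
setMethod("curveValues", "MarginCurve", function(x) x@values)

#' @rdname MarginCurve-class
#' @export
setMethod("length", "MarginCurve", function(x) length(x@values))

#' @export
setMethod("show", "MarginCurve", function(object) {
  cat("MarginCurve: W(i) for i = 1..", length(object@values),
      " (C = ", object@cost, ")\n", sep = "")
  if (any(object@skippedFolds > 0))
    cat("  degenerate folds skipped at",
        sum(object@skippedFolds > 0), "curve points\n")
})

#' @rdname SegmentedFit-class
#' @export
setMethod("residualSS", "SegmentedFit", function(x) x@rss)

#' @export
setMethod("show", "SegmentedFit", function(object) {
  cat("SegmentedFit: order-", object@degree, " polynomials meeting at c = ",
      object@breakpoint, "; rss = ",
      format(object@rss, digits = 6), "\n", sep = "")
})

#' @rdname FeatureSet-class
#' @export
setMethod("featureIndices", "FeatureSet", function(x) x@indices)

#' @rdname FeatureSet-class
#' @export
setMethod("featureSize", "FeatureSet", function(x) length(x@indices))

#' @rdname FeatureSet-class
#' @export
setMethod("geneIds", "FeatureSet", function(x) x@geneIds)

#' @export
setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet of", length(object@indices), "genes\n")
  cat("  ", paste(utils::head(object@geneIds, 8), collapse = ", "),
      if (length(object@geneIds) > 8) "..." else "", "\n", sep = "")
})
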