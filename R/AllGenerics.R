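#' @rdname ExpressionDataset-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname RelevanceList-class
#' @export
setGeneric("geneOrder", function(x) standardGeneric("geneOrder"))

#' @rdname RelevanceList-class
#' @export
setGeneric("genePValues", function(x) standardGeneric("genePValues"))

#' @rdname RelevanceList-class
#' @export
setGeneric("relevanceScores", function(x) standardGeneric("relevanceScores"))

#' @rdname Hyperplane-class
#' @export
setGeneric("marginWeights", function(x) standardGeneric("marginWeights"))

#' @rdname Hyperplane-class
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname MarginCurve-class
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname SegmentedFit-class
#' @export
setGeneric("residualSS", function(x) standardGeneric("residualSS"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureIndices", function(x) standardGeneric("featureIndices"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureSize", function(x) standardGeneric("featureSize"))
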