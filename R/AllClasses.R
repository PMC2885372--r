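#' @import methods
NULL

#' ExpressionDataset: labeled two-class expression matrix
#'
#' Container for a samples-by-genes expression matrix with a binary class
#' label per sample. Labels are always stored as -1 (normal class) and
#' +1 (cancer class); readers normalize other encodings at load time.
#'
#' @slot values numeric matrix, n samples by d genes, no missing values.
#' @slot labels numeric vector of length n with entries in \{-1, +1\}.
#' @slot geneIds character vector of d unique gene identifiers.
#' @slot sampleIds character vector of n unique sample identifiers.
#'
#' @seealso [ExpressionDataset()] for the constructor,
#'   [exprValues()], [classLabels()], [geneIds()], [sampleIds()].
#' @export
setClass("ExpressionDataset",
  representation(
    values = "matrix",
    labels = "numeric",
    geneIds = "character",
    sampleIds = "character"
  )
)

setValidity("ExpressionDataset", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "'values' contains missing or non-finite entries")
  if (length(object@labels) != nrow(v))
    msg <- c(msg, "length of 'labels' must equal the number of samples (rows)")
  if (!all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "'labels' must take values in {-1, +1}")
  if (length(object@geneIds) != ncol(v))
    msg <- c(msg, "length of 'geneIds' must equal the number of genes (columns)")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "'geneIds' must be unique")
  if (length(object@sampleIds) != nrow(v))
    msg <- c(msg, "length of 'sampleIds' must equal the number of samples")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "'sampleIds' must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param labels per-sample class labels; values in \{-1, +1\}.
#' @param geneIds gene identifiers; default taken from column names or
#'   generated as `gene1..geneD`.
#' @param sampleIds sample identifiers; default taken from row names or
#'   generated as `sample1..sampleN`.
#'
#' @return An [ExpressionDataset-class] object.
#' @examples
#' ds <- ExpressionDataset(matrix(rnorm(12), 4, 3), labels = c(-1, -1, 1, 1))
#' dim(exprValues(ds))
#' @export
ExpressionDataset <- function(values, labels, geneIds = NULL, sampleIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneIds))
    geneIds <- if (!is.null(colnames(values))) colnames(values)
               else paste0("gene", seq_len(ncol(values)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else paste0("sample", seq_len(nrow(values)))
  dimnames(values) <- NULL
  new("ExpressionDataset", values = values, labels = as.numeric(labels),
      geneIds = as.character(geneIds), sampleIds = as.character(sampleIds))
}

#' RelevanceList: gene ordering by t-test relevance
#'
#' The relevance list L orders genes by decreasing relevance, i.e. by
#' increasing two-sample t-test p-value between the two classes, ties
#' broken by the original gene index.
#'
#' @slot geneOrder integer permutation of gene indices, most relevant first.
#' @slot pvalues per-gene two-sided p-value, in original gene order.
#' @slot relevance per-gene relevance score (1 - p), in original gene order.
#' @slot geneIds gene identifiers, in original gene order.
#' @export
setClass("RelevanceList",
  representation(
    geneOrder = "integer",
    pvalues = "numeric",
    relevance = "numeric",
    geneIds = "character"
  )
)

setValidity("RelevanceList", function(object) {
  d <- length(object@pvalues)
  msg <- character()
  if (length(object@geneOrder) != d ||
      !setequal(object@geneOrder, seq_len(d)))
    msg <- c(msg, "'geneOrder' must be a permutation of 1..d")
  if (any(object@pvalues < 0 | object@pvalues > 1, na.rm = TRUE))
    msg <- c(msg, "'pvalues' must lie in [0, 1]")
  if (length(object@relevance) != d)
    msg <- c(msg, "'relevance' must have one entry per gene")
  if (length(object@geneIds) != d)
    msg <- c(msg, "'geneIds' must have one entry per gene")
  if (length(msg)) msg else TRUE
})

#' Hyperplane: linear maximum-margin decision function
#'
#' Decision function f(x) = <weights, x> + bias from a soft-margin linear
#' SVM fit; sign(f) is the predicted class.
#'
#' @slot weights numeric weight vector over the considered genes.
#' @slot bias scalar intercept.
#' @slot cost soft-margin penalty C used in the fit.
#' @slot converged logical solver status.
#' @export
setClass("Hyperplane",
  representation(
    weights = "numeric",
    bias = "numeric",
    cost = "numeric",
    converged = "logical"
  )
)

setValidity("Hyperplane", function(object) {
  if (sqrt(sum(object@weights^2)) <= 0)
    return("'weights' must have positive norm")
  if (length(object@bias) != 1)
    return("'bias' must be a scalar")
  TRUE
})

#' MarginCurve: leave-one-out error margin versus gene count
#'
#' W(i) is the leave-one-out error margin (LOOErM) of a dataset restricted
#' to its i most relevant genes, for i = 1..fMax.
#'
#' @slot values numeric vector W(1..fMax), all finite.
#' @slot cost soft-margin penalty used for all folds.
#' @slot skippedFolds integer, per curve point, count of degenerate
#'   leave-one-out folds excluded from the average.
#' @slot provenance list of bookkeeping fields (hashes, seed).
#' @export
setClass("MarginCurve",
  representation(
    values = "numeric",
    cost = "numeric",
    skippedFolds = "integer",
    provenance = "list"
  )
)

setValidity("MarginCurve", function(object) {
  if (length(object@values) < 1)
    return("curve must contain at least one point")
  if (any(!is.finite(object@values)))
    return("curve values must all be finite")
  if (length(object@skippedFolds) != length(object@values))
    return("'skippedFolds' must align with 'values'")
  TRUE
})

#' SegmentedFit: constrained two-segment polynomial fit
#'
#' Least-squares fit of two order-gamma polynomials to a margin curve,
#' the first over points i <= c and the second over i > c, constrained to
#' meet at the candidate breakpoint c. `coefRelevant` holds
#' (A1..Agamma, B) and `coefIrrelevant` holds (C1..Cgamma, D), where the
#' polynomial is A1*i + ... + Agamma*i^gamma + B (likewise C, D).
#'
#' @slot breakpoint candidate breakpoint c (gene count).
#' @slot degree polynomial order gamma.
#' @slot coefRelevant coefficients of the relevant-gene segment.
#' @slot coefIrrelevant coefficients of the irrelevant-gene segment.
#' @slot rss residual sum of squares epsilon of the constrained fit.
#' @export
setClass("SegmentedFit",
  representation(
    breakpoint = "integer",
    degree = "integer",
    coefRelevant = "numeric",
    coefIrrelevant = "numeric",
    rss = "numeric"
  )
)

setValidity("SegmentedFit", function(object) {
  g <- object@degree
  msg <- character()
  if (length(object@coefRelevant) != g + 1 ||
      length(object@coefIrrelevant) != g + 1)
    msg <- c(msg, "coefficient vectors must have length degree + 1")
  if (object@rss < -1e-8)
    msg <- c(msg, "'rss' must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: selected feature genes
#'
#' The f0 selected genes, as positions in the ORIGINAL gene order of the
#' dataset they were extracted from, in decreasing relevance.
#'
#' @slot indices integer positions of the selected genes (original order).
#' @slot geneIds the corresponding identifiers.
#' @export
setClass("FeatureSet",
  representation(
    indices = "integer",
    geneIds = "character"
  )
)

setValidity("FeatureSet", function(object) {
  if (anyDuplicated(object@indices))
    return("'indices' must be unique")
  if (length(object@geneIds) != length(object@indices))
    return("'geneIds' must align with 'indices'")
  TRUE
})
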