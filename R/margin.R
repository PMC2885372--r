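## Internal max-margin fit on a plain matrix. libsvm signs its decision
## values by factor-level order, not by the numeric labels, so the
## hyperplane is re-oriented to make y * f(x) positive for correctly
## classified samples.
fitMaxMarginMatrix <- function(x, y, cost = 1, tolerance = 0.001) {
  if (length(unique(y)) < 2)
    stop("cannot fit a classifier on single-class data")
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  f <- drop(x %*% w) + b
  if (sum(y * f) < 0) {
    w <- -w
    b <- -b
  }
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("max-margin solver returned a degenerate (zero-norm) hyperplane")
  new("Hyperplane", weights = unname(w), bias = b, cost = cost,
      converged = TRUE)
}

#' Fit a linear maximum-margin classifier
#'
#' Soft-margin linear SVM on the dataset (optionally restricted to a gene
#' subset). With separable data and a large penalty `cost` the solution
#' approaches the hard-margin optimum, where support vectors attain
#' functional margin 1.
#'
#' @param ds an [ExpressionDataset-class] with both classes present.
#' @param genes optional gene subset (column indices into `ds`); default
#'   all genes.
#' @param cost soft-margin penalty C (default 1, the conventional
#'   default of SVM implementations).
#' @param tolerance termination tolerance of the quadratic-programming
#'   solver (default 0.001); tighten (e.g. 1e-6) when margins must match
#'   the hard-margin optimum to high precision.
#' @return A [Hyperplane-class].
#' @examples
#' ds <- ExpressionDataset(matrix(c(-1, 1), 2, 1), labels = c(-1, 1))
#' h <- fitMaxMargin(ds)
#' geometricMargin(h, ds)  # 1
#' @export
fitMaxMargin <- function(ds, genes = NULL, cost = 1, tolerance = 0.001) {
  x <- ds@values
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  fitMaxMarginMatrix(x, classLabels(ds), cost, tolerance)
}

## Internal: minimum signed distance of labeled points to a hyperplane.
geometricMarginMatrix <- function(w, b, x, y, correctOnly = FALSE) {
  fm <- y * (drop(x %*% w) + b)
  if (correctOnly) fm <- fm[fm > 0]
  if (length(fm) == 0)
    stop("no correctly classified pattern; margin undefined for this fold")
  min(fm) / sqrt(sum(w^2))
}

#' Geometric margin of a hyperplane over a pattern set
#'
#' The minimum over the patterns of the signed distance
#' y * (<h, x> + b) / ||h||. With `correctOnly = TRUE` only patterns with
#' positive functional margin enter the minimum — the soft-margin
#' convention for non-separable sets, where the margin is measured from
#' the correctly classified patterns only.
#'
#' The result is invariant to positive rescaling of (h, b) and to
#' translation of all patterns by a common vector.
#'
#' @param hp a [Hyperplane-class].
#' @param ds an [ExpressionDataset-class] whose gene count (or `genes`
#'   subset) matches the hyperplane dimension.
#' @param genes optional gene subset applied to `ds` before scoring.
#' @param correctOnly restrict to correctly classified patterns.
#' @return The margin (scalar; negative when some pattern is
#'   misclassified and `correctOnly = FALSE`).
#' @export
geometricMargin <- function(hp, ds, genes = NULL, correctOnly = FALSE) {
  x <- ds@values
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (ncol(x) != length(hp@weights))
    stop("hyperplane dimension does not match the number of genes")
  geometricMarginMatrix(hp@weights, hp@bias, x, classLabels(ds), correctOnly)
}

## Internal LOO error margin on plain matrices. Returns the mean margin
## over valid folds plus the number of skipped (degenerate) folds.
looErrorMarginMatrix <- function(x, y, cost = 1) {
  n <- nrow(x)
  margins <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    yz <- y[-j]
    if (length(unique(yz)) < 2) next
    xz <- x[-j, , drop = FALSE]
    g <- tryCatch({
      hp <- fitMaxMarginMatrix(xz, yz, cost)
      geometricMarginMatrix(hp@weights, hp@bias, xz, yz, correctOnly = TRUE)
    }, error = function(e) NA_real_)
    margins[j] <- g
  }
  ok <- !is.na(margins)
  if (!any(ok))
    stop("all leave-one-out folds are degenerate")
  list(value = mean(margins[ok]), skipped = sum(!ok))
}

#' Leave-one-out error margin (LOOErM)
#'
#' For each sample j, a max-margin classifier is fit to the remaining
#' n - 1 patterns restricted to the considered genes, and its geometric
#' margin g_j is measured over those same remaining patterns (correctly
#' classified ones only, the soft-margin convention). The LOOErM is the
#' mean of the per-fold margins. Folds whose remainder contains a single
#' class, or no correctly classified pattern, are skipped and counted;
#' the mean is over the valid folds.
#'
#' @param ds an [ExpressionDataset-class] with n >= 3 samples.
#' @param genes considered gene subset F (column indices); default all.
#' @param cost soft-margin penalty C.
#' @param details if `TRUE`, return `list(value, skipped)` instead of the
#'   bare scalar.
#' @return The LOOErM scalar (or a list when `details = TRUE`).
#' @export
looErrorMargin <- function(ds, genes = NULL, cost = 1, details = FALSE) {
  if (nrow(ds@values) < 3)
    stop("leave-one-out margins need at least 3 samples")
  x <- ds@values
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  res <- looErrorMarginMatrix(x, classLabels(ds), cost)
  if (res$skipped > 0)
    message(res$skipped, " degenerate leave-one-out fold(s) skipped")
  if (details) res else res$value
}

#' Error-margin curve over nested gene subsets
#'
#' W(i) is the LOOErM of the dataset restricted to its first i genes,
#' for i = 1..fMax. The dataset must already be in relevance order (see
#' [reorderDataset()]), so that "first i genes" means "i most relevant
#' genes". Genes beyond `fMax` never influence the curve.
#'
#' @param ds a relevance-ordered [ExpressionDataset-class].
#' @param fMax number of curve points (default 100, capped at the gene
#'   count).
#' @param cost soft-margin penalty C used in every fold.
#' @return A [MarginCurve-class] of length `fMax`.
#' @export
marginCurve <- function(ds, fMax = 100, cost = 1) {
  d <- ncol(ds@values)
  if (fMax > d)
    stop("'fMax' exceeds the number of genes (", d, ")")
  x <- ds@values
  y <- classLabels(ds)
  w <- numeric(fMax)
  skipped <- integer(fMax)
  for (i in seq_len(fMax)) {
    res <- looErrorMarginMatrix(x[, seq_len(i), drop = FALSE], y, cost)
    w[i] <- res$value
    skipped[i] <- res$skipped
  }
  new("MarginCurve", values = w, cost = cost, skippedFolds = skipped,
      provenance = list(
        n = nrow(x), d = d, fMax = fMax,
        datasetFingerprint = c(dim(x), sum(x), sum(y))))
}
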