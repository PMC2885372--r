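#' Class-conditional parameters of a synthetic feature gene
#'
#' The synthetic benchmark draws feature gene i from Gaussians whose
#' means and standard deviations vary linearly with the gene index:
#' mu_i = 0.3 - i*0.05/20 and sigma_i = 0.15 - i*0.05/20 for the negative
#' class, alpha_i = 0.7 - i*0.05/20 and beta_i = sigma_i for the positive
#' class. The class-mean difference is therefore 0.4 for every feature
#' gene while the spread shrinks with i, so later feature genes carry
#' larger standardized effects.
#'
#' @param i 1-based feature gene index (vectorized).
#' @param nFeature number of feature genes (default 20); `i` must lie in
#'   `[1, nFeature]`.
#' @return data.frame with columns `i`, `mu`, `sigma`, `alpha`, `beta`.
#' @examples
#' featureGeneParams(20)  # mu 0.25, sigma 0.10, alpha 0.65, beta 0.10
#' @export
featureGeneParams <- function(i, nFeature = 20L) {
  if (any(i < 1 | i > nFeature) || any(i != as.integer(i)))
    stop("feature gene index must be an integer in [1, ", nFeature, "]")
  data.frame(i = i,
             mu = 0.3 - i * 0.05 / 20,
             sigma = 0.15 - i * 0.05 / 20,
             alpha = 0.7 - i * 0.05 / 20,
             beta = 0.15 - i * 0.05 / 20)
}

#' Generate the synthetic two-class expression benchmark
#'
#' Generates disjoint training and validation sets of `dTotal` genes. The
#' first `nFeature` genes are class-informative Gaussians parameterized by
#' [featureGeneParams()]; the remaining genes are drawn uniformly on
#' `backgroundRange` for both classes (pure background). Gaussian draws
#' are not clipped: the extraction method is translation-invariant, so
#' occasional negative values are harmless.
#'
#' Class counts: the positive class gets `ceiling(n * classBalance)`
#' training samples and `floor(n * classBalance)` validation samples, so
#' the default 25/475 split yields 13/12 and 237/238.
#'
#' @param nTrain,nValid training and validation sample counts
#'   (defaults 25 and 475).
#' @param dTotal total gene count (default 500).
#' @param nFeature number of feature genes (default 20).
#' @param classBalance fraction of positive-class samples (default 0.5).
#' @param backgroundRange range of the uniform background genes
#'   (default `c(0, 1)`).
#' @param seed optional RNG seed; with a fixed seed the output is
#'   reproduced exactly.
#' @return list with elements `train` and `valid`, both
#'   [ExpressionDataset-class] objects with genes named `gene1..geneD`
#'   (feature genes are `gene1..gene<nFeature>`).
#' @examples
#' sets <- generateSynthetic(seed = 7)
#' dim(sets$train)
#' @export
generateSynthetic <- function(nTrain = 25L, nValid = 475L, dTotal = 500L,
                              nFeature = 20L, classBalance = 0.5,
                              backgroundRange = c(0, 1), seed = NULL) {
  stopifnot(nFeature <= dTotal, nTrain >= 2, nValid >= 0,
            classBalance > 0, classBalance < 1,
            length(backgroundRange) == 2,
            backgroundRange[1] < backgroundRange[2])
  if (!is.null(seed)) set.seed(seed)
  pars <- featureGeneParams(seq_len(nFeature), nFeature)
  draw <- function(n, nPos, prefix) {
    nNeg <- n - nPos
    labels <- c(rep(-1, nNeg), rep(1, nPos))
    vals <- matrix(0, n, dTotal)
    for (i in seq_len(nFeature)) {
      vals[labels == -1, i] <- stats::rnorm(nNeg, pars$mu[i], pars$sigma[i])
      vals[labels == 1, i] <- stats::rnorm(nPos, pars$alpha[i], pars$beta[i])
    }
    nBg <- dTotal - nFeature
    if (nBg > 0)
      vals[, nFeature + seq_len(nBg)] <-
        stats::runif(n * nBg, backgroundRange[1], backgroundRange[2])
    ExpressionDataset(vals, labels,
                      geneIds = paste0("gene", seq_len(dTotal)),
                      sampleIds = paste0(prefix, seq_len(n)))
  }
  train <- draw(nTrain, ceiling(nTrain * classBalance), "train")
  valid <- if (nValid > 0)
    draw(nValid, floor(nValid * classBalance), "valid") else NULL
  list(train = train, valid = valid)
}

#' Generate an idealized piecewise-linear margin curve
#'
#' Fixture generator for breakpoint-recovery studies: the noiseless curve
#' rises with slope `slopeR` per gene up to the breakpoint `nR` and with
#' the smaller slope `slopeI` beyond it, mimicking the expected
#' error-margin curve of a dataset whose `nR` most relevant genes are the
#' true features. Optional i.i.d. Gaussian noise emulates the
#' finite-sample oscillation of measured curves.
#'
#' @param nR true breakpoint, `1 <= nR < fMax`.
#' @param fMax curve length.
#' @param slopeR,slopeI per-gene margin increments before and after the
#'   breakpoint; `slopeR > slopeI >= 0`.
#' @param noiseSd standard deviation of additive Gaussian noise
#'   (default 0, noiseless).
#' @param seed optional RNG seed.
#' @return A [MarginCurve-class] of length `fMax`.
#' @examples
#' curveValues(generateIdealCurve(20, 100, 1, 0.1))[c(20, 100)]  # 20, 28
#' @export
generateIdealCurve <- function(nR, fMax, slopeR, slopeI,
                               noiseSd = 0, seed = NULL) {
  if (nR < 1 || nR >= fMax)
    stop("breakpoint 'nR' must satisfy 1 <= nR < fMax")
  stopifnot(slopeR > slopeI, slopeI >= 0, noiseSd >= 0)
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(fMax)
  w <- ifelse(i <= nR, slopeR * i, slopeR * nR + slopeI * (i - nR))
  if (noiseSd > 0) w <- w + stats::rnorm(fMax, 0, noiseSd)
  new("MarginCurve", values = w, cost = NA_real_,
      skippedFolds = integer(fMax),
      provenance = list(kind = "ideal", nR = nR, slopeR = slopeR,
                        slopeI = slopeI, noiseSd = noiseSd))
}
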