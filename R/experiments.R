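#' Validation accuracy of a selected gene set
#'
#' Fits a linear max-margin classifier on the training set restricted to
#' the selected genes and reports the fraction of validation samples
#' whose predicted sign matches their label.
#'
#' @param train,valid [ExpressionDataset-class] objects sharing gene
#'   identifiers.
#' @param fs a nonempty [FeatureSet-class] selected from `train`.
#' @param cost soft-margin penalty C of the validation classifier
#'   (default 1, the same setting as the pipeline).
#' @return Accuracy in [0, 1].
#' @export
validationAccuracy <- function(train, valid, fs, cost = 1) {
  if (featureSize(fs) == 0)
    stop("cannot score an empty feature set")
  if (!identical(geneIds(train), geneIds(valid)))
    stop("training and validation sets must share gene identifiers")
  idx <- featureIndices(fs)
  hp <- fitMaxMargin(train, genes = idx, cost = cost)
  f <- drop(valid@values[, idx, drop = FALSE] %*% hp@weights) + hp@bias
  pred <- ifelse(f >= 0, 1, -1)
  mean(pred == classLabels(valid))
}

#' Hitting and missing (redundancy) rates
#'
#' Given the set of truly informative genes, the hitting rate is the
#' recovered fraction of the truth, r_h = f_A / |truth|, and the missing
#' (redundancy) rate is the fraction of selected genes that are not true
#' features, r_m = (f - f_A) / f, where f is the selected count and f_A
#' the number of selected true features. For an empty selection r_m is
#' undefined and reported as 0 with `empty = TRUE`.
#'
#' @param fs a [FeatureSet-class] (or integer vector of selected
#'   indices).
#' @param truth integer vector of true feature gene indices (nonempty).
#' @return list with `fA`, `hitRate`, `missRate`, `empty`.
#' @examples
#' hitMissRates(1:18, truth = 1:20)  # fA = 18, rh = 0.9, rm = 0
#' @export
hitMissRates <- function(fs, truth) {
  stopifnot(length(truth) > 0)
  sel <- if (is(fs, "FeatureSet")) featureIndices(fs) else as.integer(fs)
  fA <- length(intersect(sel, truth))
  f <- length(sel)
  list(fA = fA,
       hitRate = fA / length(truth),
       missRate = if (f == 0) 0 else (f - fA) / f,
       empty = f == 0)
}

#' Run the synthetic benchmark
#'
#' Repeats the synthetic experiment `nRuns` times: each run generates a
#' fresh training/validation pair (per-run seed `baseSeed + run`, so any
#' single run can be replayed in isolation), applies each requested
#' extraction method to the training set, and scores the selection
#' against the known truth (the first `nFeature` genes) and against the
#' validation set.
#'
#' @param methods subset of `c("ema", "ttt")`: error-margin extraction
#'   and/or the t-test filter baseline.
#' @param nRuns number of independent runs (default 100).
#' @param baseSeed base RNG seed (default 1).
#' @param fMax,degree,cost pipeline settings, see [extractFeatures()].
#' @param cutoff t-test filter threshold, see [ttestFilter()].
#' @param nTrain,nValid,dTotal,nFeature generator settings, see
#'   [generateSynthetic()].
#' @return list with `runs` (per-run data.frame: method, run, seed, f,
#'   fA, hitRate, missRate, accuracy) and `summary` (per-method
#'   aggregate from [benchmarkSummary()]).
#' @export
runSyntheticBenchmark <- function(methods = c("ema", "ttt"), nRuns = 100,
                                  baseSeed = 1, fMax = 100, degree = 2L,
                                  cost = 1, cutoff = 0.005,
                                  nTrain = 25L, nValid = 475L,
                                  dTotal = 500L, nFeature = 20L) {
  methods <- match.arg(methods, c("ema", "ttt"), several.ok = TRUE)
  stopifnot(nRuns >= 1)
  truth <- seq_len(nFeature)
  rows <- list()
  for (run in seq_len(nRuns)) {
    seed <- baseSeed + run
    sets <- generateSynthetic(nTrain = nTrain, nValid = nValid,
                              dTotal = dTotal, nFeature = nFeature,
                              seed = seed)
    for (m in methods) {
      row <- tryCatch({
        fs <- if (m == "ema")
          extractFeatures(sets$train, fMax = fMax, degree = degree,
                          cost = cost)$features
        else
          ttestFilter(sets$train, cutoff = cutoff)
        rates <- hitMissRates(fs, truth)
        acc <- if (featureSize(fs) > 0)
          validationAccuracy(sets$train, sets$valid, fs, cost = cost)
        else NA_real_
        data.frame(method = m, run = run, seed = seed,
                   f = featureSize(fs), fA = rates$fA,
                   hitRate = rates$hitRate, missRate = rates$missRate,
                   accuracy = acc, failed = FALSE)
      }, error = function(e) {
        warning("run ", run, ", method ", m, " failed: ",
                conditionMessage(e))
        data.frame(method = m, run = run, seed = seed, f = NA_integer_,
                   fA = NA_integer_, hitRate = NA_real_,
                   missRate = NA_real_, accuracy = NA_real_, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  runs <- do.call(rbind, rows)
  list(runs = runs, summary = benchmarkSummary(runs))
}

#' Aggregate per-run benchmark records
#'
#' Pure function of the per-run log: summary statistics of the selected
#' set size, true-feature recovery, hitting/redundancy rates and
#' validation accuracy per method, over the successful runs.
#'
#' @param runs per-run data.frame as produced by
#'   [runSyntheticBenchmark()] or [runSubsampleBenchmark()].
#' @return data.frame, one row per method.
#' @export
benchmarkSummary <- function(runs) {
  do.call(rbind, lapply(split(runs, runs$method), function(g) {
    ok <- g[!g$failed, , drop = FALSE]
    data.frame(
      method = g$method[1],
      nRuns = nrow(ok),
      nFailed = sum(g$failed),
      meanF = mean(ok$f), sdF = stats::sd(ok$f),
      medianF = stats::median(ok$f), minF = min(ok$f), maxF = max(ok$f),
      meanFA = mean(ok$fA),
      hitRate = mean(ok$hitRate), missRate = mean(ok$missRate),
      meanAccuracy = mean(ok$accuracy, na.rm = TRUE),
      sdAccuracy = stats::sd(ok$accuracy, na.rm = TRUE))
  }))
}

#' Run the subsampling benchmark on a fixed dataset
#'
#' The sampling-rate protocol for real datasets: per run, a stratified
#' random training subset is drawn from `ds` by picking
#' `floor(r * n_pos)` positive and `floor(r * n_neg)` negative samples.
#' When `valid` is supplied it is used as the fixed hold-out set for
#' every run; otherwise the complement of the training subset within
#' `ds` forms the validation set (so `rate = 1` is an error).
#'
#' @param ds the source [ExpressionDataset-class].
#' @param valid optional fixed validation [ExpressionDataset-class].
#' @param rate sampling rate r in (0, 1]; both `floor(r * n)` class
#'   counts must be >= 2.
#' @param nRuns number of resampling runs.
#' @param baseSeed base seed; run k uses `baseSeed + k`.
#' @param method `"ema"` or `"ttt"`.
#' @param truth optional true feature indices for hit/miss rates.
#' @param fMax,degree,cost,cutoff method settings.
#' @return list with `runs` and `summary` as in
#'   [runSyntheticBenchmark()] (hit/miss columns are NA when `truth` is
#'   not given).
#' @export
runSubsampleBenchmark <- function(ds, valid = NULL, rate, nRuns = 100,
                                  baseSeed = 1, method = c("ema", "ttt"),
                                  truth = NULL, fMax = 100, degree = 2L,
                                  cost = 1, cutoff = 0.005) {
  method <- match.arg(method)
  y <- classLabels(ds)
  pos <- which(y == 1); neg <- which(y == -1)
  nPosTr <- floor(rate * length(pos))
  nNegTr <- floor(rate * length(neg))
  if (nPosTr < 2 || nNegTr < 2)
    stop("sampling rate too small: fewer than 2 training samples in a class")
  if (is.null(valid) && (nPosTr == length(pos) || nNegTr == length(neg)))
    stop("sampling rate leaves an empty validation class; supply 'valid' ",
         "or lower the rate")
  rows <- list()
  for (run in seq_len(nRuns)) {
    seed <- baseSeed + run
    set.seed(seed)
    trIdx <- c(sample(neg, nNegTr), sample(pos, nPosTr))
    train <- ds[trIdx, ]
    vset <- if (is.null(valid)) ds[setdiff(seq_along(y), trIdx), ] else valid
    row <- tryCatch({
      fs <- if (method == "ema")
        extractFeatures(train, fMax = min(fMax, ncol(ds@values)),
                        degree = degree, cost = cost)$features
      else ttestFilter(train, cutoff = cutoff)
      rates <- if (!is.null(truth)) hitMissRates(fs, truth)
               else list(fA = NA_integer_, hitRate = NA_real_,
                         missRate = NA_real_)
      acc <- if (featureSize(fs) > 0)
        validationAccuracy(train, vset, fs, cost = cost) else NA_real_
      data.frame(method = method, run = run, seed = seed,
                 f = featureSize(fs), fA = rates$fA,
                 hitRate = rates$hitRate, missRate = rates$missRate,
                 accuracy = acc, failed = FALSE)
    }, error = function(e) {
      warning("run ", run, " failed: ", conditionMessage(e))
      data.frame(method = method, run = run, seed = seed, f = NA_integer_,
                 fA = NA_integer_, hitRate = NA_real_, missRate = NA_real_,
                 accuracy = NA_real_, failed = TRUE)
    })
    rows[[length(rows) + 1L]] <- row
  }
  runs <- do.call(rbind, rows)
  list(runs = runs, summary = benchmarkSummary(runs))
}
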