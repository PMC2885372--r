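test_that("symmetric two-point problem gives boundary at 0 and margin 1", {
  ds <- tinyDataset(matrix(c(-1, 1), 2, 1), c(-1, 1))
  hp <- fitMaxMargin(ds, cost = 1e6, tolerance = 1e-8)
  # decision boundary at x = 0: f(0) = bias must vanish
  expect_equal(bias(hp) / sqrt(sum(marginWeights(hp)^2)), 0,
               tolerance = 1e-6)
  expect_equal(geometricMargin(hp, ds), 1, tolerance = 1e-6)
})

test_that("duplicating a training pattern leaves the hyperplane unchanged", {
  set.seed(14)
  inst <- separableInstance(8, 3)
  ds <- tinyDataset(inst$x, inst$y)
  dup <- tinyDataset(inst$x[c(1, seq_len(8)), ], inst$y[c(1, seq_len(8))])
  h1 <- fitMaxMargin(ds, cost = 1e5, tolerance = 1e-8)
  h2 <- fitMaxMargin(dup, cost = 1e5, tolerance = 1e-8)
  expect_equal(marginWeights(h1), marginWeights(h2), tolerance = 1e-5)
  expect_equal(bias(h1), bias(h2), tolerance = 1e-5)
})

test_that("geometric margin equals brute-force signed distances and is scale-free", {
  set.seed(15)
  for (k in 1:10) {
    inst <- separableInstance(9, 3)
    ds <- tinyDataset(inst$x, inst$y)
    hp <- fitMaxMargin(ds)
    # direct enumeration over per-pattern signed distances
    w <- marginWeights(hp); b <- bias(hp)
    dists <- vapply(seq_len(9), function(j)
      inst$y[j] * (sum(w * inst$x[j, ]) + b) / sqrt(sum(w^2)), numeric(1))
    expect_equal(geometricMargin(hp, ds), min(dists), tolerance = 1e-12)
    # invariant to positive rescaling of (h, b)
    hp2 <- new("Hyperplane", weights = 2 * w, bias = 2 * b,
               cost = hp@cost, converged = TRUE)
    expect_equal(geometricMargin(hp2, ds), geometricMargin(hp, ds),
                 tolerance = 1e-12)
  }
})

test_that("margin is invariant to translating all patterns by a constant", {
  set.seed(16)
  inst <- separableInstance(10, 4)
  shift <- rnorm(4)
  ds <- tinyDataset(inst$x, inst$y)
  dsShift <- tinyDataset(sweep(inst$x, 2, shift, `+`), inst$y)
  m1 <- geometricMargin(fitMaxMargin(ds, cost = 1e6, tolerance = 1e-8), ds)
  m2 <- geometricMargin(fitMaxMargin(dsShift, cost = 1e6, tolerance = 1e-8),
                        dsShift)
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("correctOnly margins exclude misclassified patterns", {
  # 1-D overlapping classes: one point of each class on the wrong side
  x <- matrix(c(-2, -1, 1.5, -1.5, 1, 2), 6, 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  hp <- new("Hyperplane", weights = 1, bias = 0, cost = 1, converged = TRUE)
  ds <- tinyDataset(x, y)
  expect_equal(geometricMargin(hp, ds), -1.5)
  expect_equal(geometricMargin(hp, ds, correctOnly = TRUE), 1)
  allWrong <- tinyDataset(matrix(c(1, -1), 2, 1), c(-1, 1))
  expect_error(geometricMargin(hp, allWrong, correctOnly = TRUE),
               "no correctly classified")
})

test_that("soft-margin fit + margin agree with the hard-margin QP oracle", {
  set.seed(17)
  for (k in 1:50) {
    n <- sample(6:12, 1)
    d <- sample(2:5, 1)
    inst <- separableInstance(n, d)
    oracle <- hardMarginOracle(inst$x, inst$y)
    if (is.null(oracle)) next
    ds <- tinyDataset(inst$x, inst$y)
    hp <- fitMaxMargin(ds, cost = 1e6, tolerance = 1e-6)
    expect_equal(geometricMargin(hp, ds), oracle, tolerance = 1e-4)
  }
})

test_that("LOO error margin is a fold average, symmetric and order-invariant", {
  # 4-point symmetric set: every fold is the same problem
  x <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c(-1, -1, 1, 1)
  ds <- tinyDataset(x, y)
  val <- looErrorMargin(ds, cost = 1e6)
  fold1 <- ds[-1, ]
  g1 <- geometricMargin(fitMaxMargin(fold1, cost = 1e6), fold1,
                        correctOnly = TRUE)
  expect_equal(val, g1, tolerance = 1e-8)

  # fold-by-fold oracle on a random set
  set.seed(18)
  inst <- separableInstance(8, 2)
  ds2 <- tinyDataset(inst$x, inst$y)
  perFold <- vapply(1:8, function(j) {
    fold <- ds2[-j, ]
    geometricMargin(fitMaxMargin(fold, cost = 100), fold,
                    correctOnly = TRUE)
  }, numeric(1))
  expect_equal(looErrorMargin(ds2), mean(perFold), tolerance = 1e-12)

  # permuting the sample order changes nothing (up to solver tolerance)
  perm <- sample(8)
  expect_equal(looErrorMargin(ds2[perm, ]), looErrorMargin(ds2),
               tolerance = 1e-3)
  # separable folds with large C give a positive LOOErM
  expect_gt(looErrorMargin(ds2, cost = 1e6), 0)
})

test_that("margin curve matches independent pointwise recomputation", {
  sets <- generateSynthetic(nTrain = 12, nValid = 0, dTotal = 40,
                            nFeature = 8, seed = 19)
  rl <- buildRelevanceList(sets$train)
  ordered <- reorderDataset(sets$train, rl)
  curve <- marginCurve(ordered, fMax = 15)
  expect_length(curveValues(curve), 15)
  for (i in c(1, 7, 15))
    expect_equal(curveValues(curve)[i],
                 looErrorMargin(ordered, genes = seq_len(i)),
                 tolerance = 1e-12)
  # genes beyond fMax cannot influence the curve
  truncated <- ordered[, 1:15]
  expect_equal(curveValues(marginCurve(truncated, fMax = 15)),
               curveValues(curve), tolerance = 1e-12)
  expect_error(marginCurve(ordered, fMax = 60), "exceeds")
})

test_that("degenerate folds are skipped, not averaged as NaN", {
  # 3 samples: dropping the lone positive leaves a single-class remainder
  x <- matrix(c(-1, -0.5, 1), 3, 1)
  y <- c(-1, -1, 1)
  ds <- tinyDataset(x, y)
  res <- looErrorMargin(ds, details = TRUE)
  expect_equal(res$skipped, 1L)
  expect_true(is.finite(res$value))
})
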