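test_that("a curve built from two meeting quadratics is recovered exactly", {
  i <- 1:100
  cc <- 20
  aR <- c(0.9, -0.01)   # A1, A2
  B <- 0.3
  leftVal <- aR[1] * cc + aR[2] * cc^2 + B
  aI <- c(0.02, 0.0005)
  D <- leftVal - aI[1] * cc - aI[2] * cc^2   # continuity by construction
  w <- ifelse(i <= cc, aR[1] * i + aR[2] * i^2 + B,
              aI[1] * i + aI[2] * i^2 + D)
  fit <- segmentedFit(w, cc, degree = 2)
  expect_lt(residualSS(fit), 1e-16 * sum(w^2))
  expect_equal(fit@coefRelevant, c(aR, B), tolerance = 1e-6)
  expect_equal(fit@coefIrrelevant, c(aI, D), tolerance = 1e-6)
  expect_equal(predictSegmented(fit, i), w, tolerance = 1e-6)
})

test_that("the constrained fit satisfies continuity at every breakpoint", {
  set.seed(23)
  w <- curveValues(generateIdealCurve(15, 60, 0.8, 0.05, noiseSd = 0.05,
                                      seed = 23))
  for (cc in c(3, 15, 30, 57)) {
    fit <- segmentedFit(w, cc, degree = 2)
    gR <- predictSegmented(fit, cc)
    fitI <- fit@coefIrrelevant
    gI <- fitI[1] * cc + fitI[2] * cc^2 + fitI[3]
    expect_lt(abs(gR - gI), 1e-8 * max(1, abs(gR)))
  }
})

test_that("segmented fit matches the Lagrange-multiplier oracle", {
  set.seed(24)
  for (k in 1:40) {
    fMax <- sample(30:80, 1)
    degree <- sample(1:3, 1)
    cc <- sample((degree + 1):(fMax - degree), 1)
    w <- cumsum(runif(fMax, 0, 0.2)) + rnorm(fMax, 0, 0.05)
    fit <- segmentedFit(w, cc, degree)
    oracle <- constrainedLSOracle(w, cc, degree)
    expect_equal(residualSS(fit), oracle$rss,
                 tolerance = 1e-8 * max(1, oracle$rss))
    # the raw power basis is nearly collinear at degree 3, so individual
    # coefficients are resolved less sharply than the residual
    expect_equal(c(fit@coefRelevant, fit@coefIrrelevant),
                 unname(oracle$theta), tolerance = 1e-4)
  }
})

test_that("fit is optimal against random feasible coefficient pairs", {
  set.seed(25)
  w <- curveValues(generateIdealCurve(20, 60, 1, 0.1, noiseSd = 0.1,
                                      seed = 25))
  cc <- 25
  fit <- segmentedFit(w, cc, degree = 2)
  i <- 1:60
  for (k in 1:50) {
    # random feasible candidate: free A, B, C; D forced by continuity
    A <- fit@coefRelevant[1:2] + rnorm(2, 0, 0.05)
    B <- fit@coefRelevant[3] + rnorm(1, 0, 0.05)
    C <- fit@coefIrrelevant[1:2] + rnorm(2, 0, 0.05)
    D <- (A[1] * cc + A[2] * cc^2 + B) - (C[1] * cc + C[2] * cc^2)
    pred <- ifelse(i <= cc, A[1] * i + A[2] * i^2 + B,
                   C[1] * i + C[2] * i^2 + D)
    expect_gte(sum((w - pred)^2), residualSS(fit) - 1e-10)
  }
})

test_that("degenerate curves: flat curve fits exactly, ties break small", {
  fitFlat <- segmentedFit(rep(5, 40), 10, degree = 2)
  expect_lt(residualSS(fitFlat), 1e-20)
  expect_equal(fitFlat@coefRelevant, c(0, 0, 5), tolerance = 1e-7)
  expect_equal(fitFlat@coefIrrelevant, c(0, 0, 5), tolerance = 1e-7)
  # a single global quadratic fits at every candidate: smallest c wins
  i <- 1:50
  w <- 0.3 + 0.05 * i - 0.0004 * i^2
  cp <- findCriticalPoint(w, degree = 2)
  expect_equal(cp$f0, 3L)
})

test_that("noiseless piecewise-linear fixture yields the exact breakpoint", {
  curve <- generateIdealCurve(20, 100, 1, 0.1)
  cp <- findCriticalPoint(curve, degree = 2)
  expect_equal(cp$f0, 20L)
  expect_lt(residualSS(cp$fit), 1e-16 * sum(curveValues(curve)^2))
  # epsilon is strictly positive away from the truth
  away <- cp$profile$epsilon[cp$profile$f %in% c(10, 40)]
  expect_true(all(away > 1e-6))
})

test_that("breakpoint recovery is robust to small curve noise", {
  hits <- vapply(1:100, function(s) {
    curve <- generateIdealCurve(20, 100, 1, 0.1, noiseSd = 0.01, seed = s)
    findCriticalPoint(curve, degree = 2)$f0
  }, integer(1))
  expect_gte(mean(abs(hits - 20) <= 2), 0.90)
})

test_that("curve translation and scaling act on the fit as expected", {
  w <- curveValues(generateIdealCurve(12, 50, 0.7, 0.08, noiseSd = 0.05,
                                      seed = 26))
  cp <- findCriticalPoint(w)
  shifted <- findCriticalPoint(w + 3)
  expect_equal(shifted$f0, cp$f0)
  expect_equal(residualSS(shifted$fit), residualSS(cp$fit),
               tolerance = 1e-8 * max(1, residualSS(cp$fit)))
  # intercepts absorb the shift
  expect_equal(shifted$fit@coefRelevant[3], cp$fit@coefRelevant[3] + 3,
               tolerance = 1e-6)
  scaled <- findCriticalPoint(2 * w)
  expect_equal(scaled$f0, cp$f0)
  expect_equal(residualSS(scaled$fit), 4 * residualSS(cp$fit),
               tolerance = 1e-8 * max(1, residualSS(cp$fit)))
})

test_that("ill-posed breakpoints and ranges are rejected", {
  w <- curveValues(generateIdealCurve(10, 30, 1, 0.1))
  expect_error(segmentedFit(w, 2, degree = 2), "under-determined")
  expect_error(segmentedFit(w, 29, degree = 2), "under-determined")
  expect_error(findCriticalPoint(w, cRange = c(40, 50)), "candidate")
})
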