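#' Constrained two-segment polynomial fit at a candidate breakpoint
#'
#' Fits order-`degree` polynomials G(i | A, B) = sum_k A_k i^k + B to the
#' curve points i <= c and G(i | C, D) = sum_k C_k i^k + D to the points
#' i > c, minimizing the total squared error subject to the continuity
#' constraint G(c | A, B) = G(c | C, D). The constraint is eliminated by
#' substituting D = G(c | A, B) - sum_k C_k c^k into the objective, which
#' leaves an ordinary linear least-squares problem in
#' (A_1..A_gamma, B, C_1..C_gamma) solved by QR; D is then recovered from
#' the constraint. This is algebraically the normal-equation solve
#' Psi = M^-1 Y for the joint coefficient vector.
#'
#' @param curve a [MarginCurve-class] (or bare numeric vector W(1..fMax)).
#' @param breakpoint candidate breakpoint c, with
#'   `degree + 1 <= c <= fMax - degree` so both segments are
#'   identifiable.
#' @param degree polynomial order gamma >= 1 (default 2).
#' @return A [SegmentedFit-class]; its `rss` slot is the estimation error
#'   epsilon(c).
#' @examples
#' w <- generateIdealCurve(20, 100, 1, 0.1)
#' residualSS(segmentedFit(w, 20))    # ~0: true breakpoint
#' residualSS(segmentedFit(w, 50))    # > 0
#' @export
segmentedFit <- function(curve, breakpoint, degree = 2L) {
  w <- if (is(curve, "MarginCurve")) curveValues(curve) else as.numeric(curve)
  fMax <- length(w)
  degree <- as.integer(degree)
  cc <- as.integer(breakpoint)
  if (degree < 1) stop("'degree' must be >= 1")
  if (cc < degree + 1 || cc > fMax - degree)
    stop("breakpoint c = ", cc, " leaves an under-determined segment; ",
         "need ", degree + 1, " <= c <= ", fMax - degree)
  i <- seq_len(fMax)
  powers <- outer(i, seq_len(degree), `^`)          # i^k, k = 1..gamma
  cpow <- cc^seq_len(degree)
  left <- i <= cc
  # columns: A_1..A_gamma, B, C_1..C_gamma (D eliminated by continuity)
  X <- matrix(0, fMax, 2 * degree + 1)
  X[left, seq_len(degree)] <- powers[left, , drop = FALSE]
  X[left, degree + 1] <- 1
  X[!left, seq_len(degree)] <- rep(cpow, each = sum(!left))
  X[!left, degree + 1] <- 1
  X[!left, degree + 1 + seq_len(degree)] <-
    powers[!left, , drop = FALSE] - rep(cpow, each = sum(!left))
  fit <- stats::lm.fit(X, w)
  if (fit$rank < ncol(X))
    stop("singular normal equations at c = ", cc, ", degree = ", degree,
         " (collinear design; is the curve long enough?)")
  theta <- fit$coefficients
  A <- theta[seq_len(degree)]
  B <- theta[degree + 1]
  C <- theta[degree + 1 + seq_len(degree)]
  D <- sum(A * cpow) + B - sum(C * cpow)
  rss <- sum(fit$residuals^2)
  new("SegmentedFit", breakpoint = cc, degree = degree,
      coefRelevant = unname(c(A, B)), coefIrrelevant = unname(c(C, D)),
      rss = rss)
}

#' Evaluate a segmented fit
#'
#' @param fit a [SegmentedFit-class].
#' @param i positions at which to evaluate the fitted curve; points
#'   `i <= c` use the relevant-segment polynomial, points `i > c` the
#'   irrelevant-segment one.
#' @return Fitted values.
#' @export
predictSegmented <- function(fit, i) {
  g <- fit@degree
  powers <- outer(i, seq_len(g), `^`)
  left <- drop(powers %*% fit@coefRelevant[seq_len(g)]) +
    fit@coefRelevant[g + 1]
  right <- drop(powers %*% fit@coefIrrelevant[seq_len(g)]) +
    fit@coefIrrelevant[g + 1]
  ifelse(i <= fit@breakpoint, left, right)
}

#' Estimate the critical point of a margin curve
#'
#' Scans candidate breakpoints, fits the continuity-constrained
#' two-segment polynomial at each, and returns the candidate with the
#' minimum estimation error epsilon. Candidates whose epsilon is within a
#' tiny relative tolerance of the minimum are treated as exact ties
#' (a curve that a single global polynomial fits has epsilon ~ 0 at every
#' candidate, differing only in rounding noise); ties resolve to the
#' smallest candidate, the parsimonious choice.
#'
#' Candidates leaving fewer than `degree + 1` points in a segment are
#' under-determined and excluded from the scan, so the effective default
#' range is `[degree + 1, fMax - degree]`.
#'
#' @param curve a [MarginCurve-class] (or numeric vector).
#' @param degree polynomial order gamma (default 2).
#' @param cRange optional candidate interval `c(lo, hi)`; intersected
#'   with the well-posed range.
#' @return list with elements `f0` (the estimated breakpoint), `fit` (the
#'   [SegmentedFit-class] at `f0`) and `profile` (data.frame of `f`,
#'   `epsilon` over all scanned candidates).
#' @examples
#' findCriticalPoint(generateIdealCurve(20, 100, 1, 0.1))$f0  # 20
#' @export
findCriticalPoint <- function(curve, degree = 2L, cRange = NULL) {
  w <- if (is(curve, "MarginCurve")) curveValues(curve) else as.numeric(curve)
  fMax <- length(w)
  degree <- as.integer(degree)
  lo <- degree + 1L
  hi <- fMax - degree
  if (!is.null(cRange)) {
    lo <- max(lo, as.integer(cRange[1]))
    hi <- min(hi, as.integer(cRange[2]))
  }
  if (lo > hi)
    stop("no well-posed breakpoint candidate in the requested range")
  cand <- lo:hi
  fits <- vector("list", length(cand))
  eps <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    fits[[k]] <- tryCatch(segmentedFit(w, cand[k], degree),
                          error = function(e) NULL)
    if (!is.null(fits[[k]])) eps[k] <- fits[[k]]@rss
  }
  ok <- !is.na(eps)
  if (!any(ok))
    stop("segmented fit failed at every candidate breakpoint")
  # near-ties at the numerical noise floor resolve to the smallest c
  tieTol <- 1e-10 * (sum(w^2) + .Machine$double.eps)
  best <- which(ok & eps <= min(eps[ok]) + tieTol)[1]
  list(f0 = cand[best], fit = fits[[best]],
       profile = data.frame(f = cand, epsilon = eps))
}
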