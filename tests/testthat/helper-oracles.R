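# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exact hard-margin linear SVM by support-set enumeration: for every
# candidate support subset solve the KKT equality system and keep the one
# that is dual-feasible (alphas >= 0) and primal-feasible (all functional
# margins >= 1). Returns the geometric margin 1/||w||, or NULL if no
# separating KKT point exists (non-separable input).
hardMarginOracle <- function(x, y) {
  n <- nrow(x)
  d <- ncol(x)
  K <- x %*% t(x)
  for (m in 2:min(d + 1, n)) {
    for (S in utils::combn(n, m, simplify = FALSE)) {
      ys <- y[S]
      if (length(unique(ys)) < 2) next
      A <- rbind(cbind(sweep(K[S, S, drop = FALSE], 2, ys, `*`), 1),
                 c(ys, 0))
      sol <- tryCatch(solve(A, c(1 / ys, 0)), error = function(e) NULL)
      if (is.null(sol)) next
      a <- sol[seq_len(m)]
      b <- sol[m + 1]
      if (any(a < -1e-9)) next
      w <- drop(t(x[S, , drop = FALSE]) %*% (a * ys))
      if (all(y * (drop(x %*% w) + b) >= 1 - 1e-7))
        return(1 / sqrt(sum(w^2)))
    }
  }
  NULL
}

# Equality-constrained least squares by the KKT (Lagrange multiplier)
# system, on the FULL parameterization (A_1..A_g, B, C_1..C_g, D) with
# the continuity constraint at c handled explicitly. The system is built
# on the scaled index t = i / fMax (the raw-power KKT matrix is
# numerically singular for degree 3 at fMax ~ 100) and the coefficients
# are mapped back to the raw-index scale. Returns the residual sum of
# squares and the coefficient vector.
constrainedLSOracle <- function(w, cc, degree) {
  fMax <- length(w)
  t <- seq_len(fMax) / fMax
  tc <- cc / fMax
  powers <- outer(t, seq_len(degree), `^`)
  left <- seq_len(fMax) <= cc
  p <- 2 * (degree + 1)
  Z <- matrix(0, fMax, p)
  Z[left, seq_len(degree)] <- powers[left, , drop = FALSE]
  Z[left, degree + 1] <- 1
  Z[!left, degree + 1 + seq_len(degree)] <- powers[!left, , drop = FALSE]
  Z[!left, p] <- 1
  a <- c(tc^seq_len(degree), 1, -(tc^seq_len(degree)), -1)
  kkt <- rbind(cbind(2 * crossprod(Z), a), c(a, 0))
  rhs <- c(2 * crossprod(Z, w), 0)
  sol <- solve(kkt, rhs)
  theta <- sol[seq_len(p)]
  scale <- c(fMax^seq_len(degree), 1)
  list(rss = sum((w - drop(Z %*% theta))^2),
       theta = theta / c(scale, scale))
}

# Random separable two-class instance on d genes.
separableInstance <- function(n, d, gap = 6) {
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- c(rep(-1, floor(n / 2)), rep(1, ceiling(n / 2)))
  x[y == 1, 1] <- x[y == 1, 1] + gap
  list(x = x, y = y)
}

# Small labeled dataset fixture.
tinyDataset <- function(values, labels) {
  ExpressionDataset(as.matrix(values), labels)
}
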