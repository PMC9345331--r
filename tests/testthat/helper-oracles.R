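# Independent oracles used across the suite. These deliberately take a
# different computational route from the package code they check.

# Generic equality-constrained quadratic program:
#   minimize (w - d)' D^{-1} (w - d)  subject to  A' w = b,  D = diag(d)
# solved via the full (n + k) KKT linear system in one shot. The package's
# GREG solver instead uses the reduced normal equations in lambda.
qp_equality_oracle <- function(d, A, b) {
  n <- length(d)
  k <- ncol(A)
  KKT <- rbind(cbind(diag(2 / d, n), A),
               cbind(t(A), matrix(0, k, k)))
  rhs <- c(2 / d * d, b)
  sol <- solve(KKT, rhs)
  sol[seq_len(n)]
}

# Order-statistic linear-interpolation quantile (type-7 convention),
# written out directly rather than via stats::quantile.
quantile_interp_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Compound growth computed by repeated multiplication (loop), as an
# arithmetic oracle for closed-form (1+g)^t indexation and benchmarks.
compound_growth_oracle <- function(value, g, t) {
  for (i in seq_len(t)) value <- value * (1 + g)
  value
}
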