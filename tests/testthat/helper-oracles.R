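# Independent oracles used to cross-validate the envelopment LP.

# Exact brute-force solution of the output-oriented envelopment problem
# for small n: enumerate all candidate vertices of the feasible polytope
# in (lambda, theta) by choosing active-constraint sets, solve each
# square linear system, keep the feasible vertex with maximal theta.
# Exponential in n; intended for n <= ~12.
vertex_enum_oracle <- function(X, Y, dmu_index, vrs = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  x0 <- X[dmu_index, ]; y0 <- Y[dmu_index, ]
  d <- n + 1                      # variables: lambda_1..n, theta
  # inequality rows A v >= b
  A <- rbind(cbind(t(Y), -y0),    # outputs: Y'l - th*y0 >= 0
             cbind(-t(X), rep(0, p)),  # inputs: -X'l >= -x0
             diag(d))             # lambda >= 0, theta >= 0
  b <- c(rep(0, q), -x0, rep(0, d))
  scale_row <- pmax(apply(abs(cbind(A, b)), 1, max), 1e-12)
  A <- A / scale_row; b <- b / scale_row
  eq <- c(rep(1, n), 0)           # sum lambda = 1 (VRS only)
  n_active <- if (vrs) n else d   # eq row supplies one active constraint
  best <- -Inf
  for (comb in utils::combn(nrow(A), n_active, simplify = FALSE)) {
    M <- A[comb, , drop = FALSE]
    rhs <- b[comb]
    if (vrs) { M <- rbind(eq, M); rhs <- c(1, rhs) }
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (all(A %*% v >= b - 1e-8) &&
        (!vrs || abs(sum(v[seq_len(n)]) - 1) < 1e-8))
      best <- max(best, v[d])
  }
  best
}

# Reference Silverman bandwidth on the reflected sample, written straight
# from the rule-of-thumb formula (independent of the package code path).
silverman_reflected_reference <- function(theta) {
  refl <- c(theta, 2 - theta)
  0.9 * min(stats::sd(refl), stats::IQR(refl) / 1.34) *
    (length(refl))^(-1 / 5)
}

rmse_ref <- function(a, b) sqrt(mean((a - b)^2))
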