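# Internal dense linear algebra helpers. All operate on plain base matrices;
# sizes here are at most a few hundred, so eigendecomposition-based routes are
# both fast and adequate.

# Moore-Penrose pseudo-inverse with relative singular-value cutoff.
pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Solve the continuous-time Lyapunov equation W C + C W' + Q = 0 for C.
# Uses the eigendecomposition of W (complex-safe); falls back to the
# Kronecker-product linear system if W is numerically defective.
lyapunov_solve <- function(W, Q) {
  n <- nrow(W)
  stopifnot(ncol(W) == n, all(dim(Q) == n))
  e <- eigen(W)
  V <- e$vectors
  ok <- tryCatch({
    Vi <- solve(V)
    TRUE
  }, error = function(e) FALSE)
  if (ok && min(svd(V)$d) > 1e-10 * max(svd(V)$d)) {
    Qt <- Vi %*% Q %*% Conj(t(Vi))
    denom <- outer(e$values, Conj(e$values), `+`)
    X <- -Qt / denom
    C <- V %*% X %*% Conj(t(V))
    C <- Re(C)
  } else {
    K <- kronecker(diag(n), W) + kronecker(W, diag(n))
    C <- matrix(solve(K, -as.vector(Q)), n, n)
  }
  (C + t(C)) / 2
}

# Matrix exponential through the eigendecomposition of A (real part taken;
# valid for diagonalizable A, which random stable drifts are in practice).
expm_eig <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% (exp(e$values) * solve(e$vectors)))
}

# Symmetric PSD square root; negative eigenvalues (numerical) clipped at 0.
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

sym_check <- function(M, tol = 1e-8, what = "matrix") {
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(what, " is not symmetric within tolerance")
  (M + t(M)) / 2
}
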