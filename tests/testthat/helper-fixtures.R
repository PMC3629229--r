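# Shared fixtures: everything is generated in code, nothing is read from disk.

# A tiny stable drift with known entries (3 nodes, damped rotation + leak).
fixed_W3 <- function() {
  matrix(c(-4,  2,  0,
           -2, -4,  1,
            0, -1, -3), 3, 3, byrow = TRUE)
}

# Small simulated recording driven by a known (W, Q).
sim_rec <- function(n = 5, duration = 10, seed = 1, dt = 1 / 625,
                    target = -2.5, Q = NULL) {
  W <- random_stable_connectivity(n, target, seed = seed)
  if (is.null(Q)) Q <- diag(n)
  list(W = W, Q = Q,
       rec = simulate_moup(W, Q, dt = dt, duration = duration,
                           seed = seed + 1000))
}

# Small fitted two-group cohort for classification/statistics tests.
small_cohort <- function(n_control = 5, n_patient = 5, n_channels = 8,
                         duration = 6, deltas = data.frame(i = 3, j = 1, delta = 4),
                         ell_control = 0.06, ell_patient = 0.18, seed = 7) {
  spec <- cohort_spec(n_control = n_control, n_patient = n_patient,
                      layout = synthetic_layout(n_channels),
                      deltas = deltas, ell_control = ell_control,
                      ell_patient = ell_patient, duration = duration,
                      seed = seed)
  fit_cohort(synthesize_cohort(spec))
}

# Independent leave-one-out biharmonic interpolation reference: plain loops,
# explicit linear system with affine side conditions, used as the oracle for
# spatial_complexity.
reference_complexity <- function(x, P) {
  n <- length(x)
  g <- function(r) if (r == 0) 0 else r^2 * (log(r) - 1)
  errs <- numeric(n)
  for (s in seq_len(n)) {
    idx <- setdiff(seq_len(n), s)
    m <- length(idx)
    A <- matrix(0, m + 3, m + 3)
    for (a in seq_len(m)) for (b in seq_len(m))
      A[a, b] <- g(sqrt(sum((P[idx[a], ] - P[idx[b], ])^2)))
    for (a in seq_len(m)) {
      A[a, m + 1:3] <- c(1, P[idx[a], 1], P[idx[a], 2])
      A[m + 1:3, a] <- c(1, P[idx[a], 1], P[idx[a], 2])
    }
    coef <- solve(A, c(x[idx], 0, 0, 0))
    pred <- coef[m + 1] + coef[m + 2] * P[s, 1] + coef[m + 3] * P[s, 2]
    for (a in seq_len(m))
      pred <- pred + coef[a] * g(sqrt(sum((P[s, ] - P[idx[a], ])^2)))
    errs[s] <- x[s] - pred
  }
  sqrt(mean(errs^2))
}

# Exhaustive two-sided permutation p-value for the difference of means.
exhaustive_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); N <- length(pooled)
  obs <- mean(a) - mean(b)
  parts <- utils::combn(N, n)
  diffs <- apply(parts, 2, function(ix)
    mean(pooled[ix]) - mean(pooled[-ix]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}
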