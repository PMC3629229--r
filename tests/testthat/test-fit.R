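test_that("estimate_connectivity recovers a known 3x3 drift from AR(1) data", {
  # data generated exactly by x(t+1) = (I + tau W0) x(t) + tiny noise
  W0 <- fixed_W3()
  dt <- 1 / 625
  A <- diag(3) + dt * W0
  T <- 5 * 60 * 625
  set.seed(10)
  X <- matrix(0, 3, T)
  x <- rnorm(3)
  E <- 0.05 * matrix(rnorm(3 * T), 3, T)
  for (t in seq_len(T)) { x <- A %*% x + E[, t]; X[, t] <- x }
  rec <- center_signals(mc_recording(X, dt = dt))
  What <- estimate_connectivity(rec, 1)$W
  expect_lt(norm(What - W0, "F") / norm(W0, "F"), 0.1)
})

test_that("temporally i.i.d. data drives the estimate toward -I", {
  T <- 50000
  set.seed(11)
  rec <- center_signals(mc_recording(matrix(rnorm(3 * T), 3, T), dt = 1))
  What <- estimate_connectivity(rec, 1)$W
  expect_lt(max(abs(What + diag(3))), 0.05)
})

test_that("the estimator equals (C(tau) C(0)^-1 - I)/tau computed independently", {
  set.seed(12)
  rec <- center_signals(mc_recording(matrix(rnorm(2 * 400), 2, 400), dt = 0.5))
  What <- estimate_connectivity(rec, 1)$W
  # independent arithmetic: covariances computed by hand
  X <- rec$data; T <- ncol(X)
  C0 <- tcrossprod(X) / (T - 1)
  C1 <- tcrossprod(X[, 2:T], X[, 1:(T - 1)]) / (T - 2)
  expect_equal(unname(What), (C1 %*% solve(C0) - diag(2)) / 0.5,
               tolerance = 1e-10, ignore_attr = TRUE)
  # scalar reading: diagonal of a diagonal-W fit obeys (a - 1)/tau entrywise
})

test_that("all-zero data is a degenerate input", {
  rec <- mc_recording(matrix(0, 2, 100) + 1e-300 * 0, dt = 1)
  expect_error(estimate_connectivity(center_signals(rec), 1), "degenerate")
})

test_that("rank-deficient C(0) falls back to the pseudo-inverse", {
  set.seed(13)
  x <- rnorm(1000)
  rec <- center_signals(mc_recording(matrix(c(x, x, rnorm(1000)), 3,
                                            byrow = TRUE), dt = 1))
  expect_silent(W <- estimate_connectivity(rec, 1))
  expect_true(all(is.finite(W$W)))
})

test_that("select_lag: single candidate, brute-force agreement, simulated minimum", {
  s <- sim_rec(n = 5, duration = 8, seed = 20)
  rec <- center_signals(s$rec)
  expect_identical(as.integer(select_lag(rec, 3L)), 3L)

  # brute-force oracle: recompute residual-covariance traces independently
  cands <- c(1L, 2L, 4L, 8L)
  oracle <- sapply(cands, function(l) {
    tau <- l * rec$dt; T <- ncol(rec$data)
    W <- estimate_connectivity(rec, l)$W
    X <- rec$data[, 1:(T - l)]; Xf <- rec$data[, (1 + l):T]
    R <- (Xf - X) / tau - W %*% X
    R <- R - rowMeans(R)
    sum(diag(tau * tcrossprod(R) / (ncol(R) - 1)))
  })
  picked <- select_lag(rec, cands)
  expect_identical(as.integer(picked), cands[which.min(oracle)])
  # Note: on exactly linear simulated data the residual trace decreases with
  # the lag, so the selector prefers the largest candidate here; the
  # smallest-lag minimum reported on real recordings reflects real-data
  # departures from the model (see the methods vignette). The package
  # therefore fits at lag 1 by default rather than auto-selecting.

  # a forced optimum: data built as an exact 2-step linear recursion plus
  # noise that is white at lag 2 -- lag 2 must win over lag 1 and 3
  set.seed(21)
  A2 <- diag(2) * 0.99
  X <- matrix(0, 2, 4000); x <- rnorm(2)
  E <- matrix(rnorm(2 * 4000, sd = 0.2), 2)
  for (t in 1:4000) { x <- if (t > 2) A2 %*% X[, t - 2] + E[, t] else rnorm(2); X[, t] <- x }
  rec2 <- center_signals(mc_recording(X, dt = 1))
  oracle2 <- sapply(1:3, function(l) {
    W <- estimate_connectivity(rec2, l)$W
    nm <- extract_residuals(rec2, W, l)
    sum(diag(empirical_noise_covariance(nm, l, 1)))
  })
  expect_identical(as.integer(select_lag(rec2, 1:3)), which.min(oracle2))
})

test_that("residuals vanish on exact linear recursions and collapse for W = 0", {
  W0 <- fixed_W3(); dt <- 0.01
  A <- diag(3) + dt * W0
  X <- matrix(0, 3, 200); x <- c(1, -1, 0.5)
  for (t in 1:200) { x <- A %*% x; X[, t] <- x }
  rec <- mc_recording(X, dt = dt)
  nm <- extract_residuals(rec, W0, 1)
  expect_lt(max(abs(nm$residuals)), 1e-10)

  rec2 <- mc_recording(matrix(rnorm(40), 2, 20), dt = 1)
  nm2 <- extract_residuals(rec2, matrix(0, 2, 2), 1)
  expect_equal(nm2$residuals, rec2$data[, 2:20] - rec2$data[, 1:19],
               ignore_attr = TRUE)
  expect_error(extract_residuals(rec2, matrix(0, 3, 3), 1), "dimensions")
})

test_that("empirical Q: scaling arithmetic and simulated diffusion recovery", {
  # zero residuals -> zero matrix
  rec <- mc_recording(matrix(rep(c(1, 2), each = 50), 2, 50, byrow = TRUE), dt = 1)
  nm0 <- extract_residuals(center_signals(rec), diag(c(0, 0)), 1)
  nm0$residuals[] <- 0
  expect_equal(empirical_noise_covariance(nm0), matrix(0, 2, 2),
               ignore_attr = TRUE)

  # variance v at tau = 1/625 scales to v/625
  set.seed(30)
  nm <- structure(list(residuals = matrix(rnorm(2 * 5000), 2, 5000),
                       dt = 1 / 625, lag_steps = 1L,
                       channel_ids = c("a", "b")), class = "noise_model")
  Q <- empirical_noise_covariance(nm)
  v <- apply(nm$residuals, 1, var)
  expect_equal(diag(Q), v / 625, tolerance = 1e-12, ignore_attr = TRUE)

  # scalar OU, lambda = 5, q = 2: Q_E recovers q (two independent channels)
  lam <- 5; q <- 2
  rec <- simulate_moup(diag(-lam, 2), diag(q, 2), dt = 1 / 625,
                       duration = 60, seed = 31)
  f <- fit_subject(rec)
  expect_equal(unname(diag(f$noise$Q_empirical)), c(q, q), tolerance = 0.1 * q)

  # simulated mOUP with known diffusion: residual covariance * tau ~ Q0
  s <- sim_rec(n = 4, duration = 30, seed = 32, Q = diag(c(1, 2, 3, 4)))
  f2 <- fit_subject(s$rec)
  expect_equal(unname(diag(f2$noise$Q_empirical)), c(1, 2, 3, 4),
               tolerance = 0.1 * 4)
})

test_that("theoretical Q: scalar and diagonal identities, Lyapunov round trip", {
  # scalar Lyapunov identity: W = -lambda, C0 = sigma^2 -> Q = 2 lambda sigma^2
  expect_equal(theoretical_noise_covariance(matrix(-3, 1, 1), matrix(2, 1, 1)),
               matrix(12, 1, 1), ignore_attr = TRUE)
  expect_equal(theoretical_noise_covariance(diag(c(-1, -2)), diag(c(3, 5))),
               diag(c(6, 20)), ignore_attr = TRUE)

  # random stable 4x4 W and PSD Q0: solve Lyapunov for C, then recover Q0
  W <- random_stable_connectivity(4, -2, seed = 40)$W
  set.seed(41)
  B <- matrix(rnorm(16), 4)
  Q0 <- crossprod(B) + diag(4)
  C <- ouconn:::lyapunov_solve(W, Q0)
  expect_equal(theoretical_noise_covariance(W, C), Q0, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_warning(theoretical_noise_covariance(diag(c(1, -1)), diag(2)),
                 "not stable")
})

test_that("noise agreement: identities and degenerate flag", {
  set.seed(50)
  Q <- crossprod(matrix(rnorm(9), 3))
  expect_equal(noise_agreement(Q, Q), 1)
  expect_equal(noise_agreement(Q, -Q), -1)
  flagged <- noise_agreement(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_true(is.nan(flagged))
  expect_true(attr(flagged, "degenerate"))
})

test_that("stability spectrum: closed forms and the stable flag", {
  r1 <- stability_spectrum(-diag(3))
  expect_equal(r1$max_real_part, -1)
  expect_true(r1$stable)
  r2 <- stability_spectrum(matrix(c(0, -1, 1, 0), 2))
  expect_equal(r2$max_real_part, 0)
  expect_false(r2$stable)
  expect_equal(r2$max_real_part, max(Re(r2$eigenvalues)))
})

test_that("residual diagnostics: gaussian white, AR(1), lag-0 normalization", {
  T <- 20000
  set.seed(60)
  nm <- structure(list(residuals = matrix(rnorm(6 * T), 6, T), dt = 1,
                       lag_steps = 1L, channel_ids = letters[1:6]),
                  class = "noise_model")
  d <- residual_diagnostics(nm, max_lag = 20)
  expect_equal(max(abs(d$autocorrelation[, 1] - 1)), 0, tolerance = 1e-12)
  expect_lt(d$whiteness_score, 4 / sqrt(T))
  expect_true(all(abs(d$skewness) < 0.2))
  expect_gt(max(d$normality_p), 0.1)      # p spread over (0, 1), not all tiny
  expect_gt(min(d$normality_p), 1e-4)

  set.seed(61)
  ar <- replicate(2, as.numeric(stats::arima.sim(list(ar = 0.9), T)))
  nm2 <- structure(list(residuals = t(ar), dt = 1, lag_steps = 1L,
                        channel_ids = c("a", "b")), class = "noise_model")
  d2 <- residual_diagnostics(nm2, max_lag = 5)
  expect_equal(d2$whiteness_score, 0.9, tolerance = 0.03)
  expect_equal(unname(d2$autocorrelation[1, 2]), 0.9, tolerance = 0.03)
})

test_that("scalar OU drift bias is O(lambda tau) on a lag grid", {
  lam <- 5
  rec <- simulate_moup(diag(-lam, 2), diag(2, 2), dt = 1 / 625,
                       duration = 320, seed = 70)
  rec <- center_signals(rec)
  lags <- c(8L, 16L, 32L, 64L)
  est <- sapply(lags, function(l) mean(diag(estimate_connectivity(rec, l)$W)))
  tau <- lags / 625
  closed <- (exp(-lam * tau) - 1) / tau   # population value of the estimator
  # estimates match the closed form within sampling error
  expect_lt(max(abs(est - closed)), 0.15)
  # and the closed-form bias grows like lambda^2 tau / 2
  bias <- closed + lam
  expect_true(all(abs(bias) / (lam^2 * tau / 2) > 0.5 &
                  abs(bias) / (lam^2 * tau / 2) < 1.5))
  expect_true(all(diff(abs(bias)) > 0))
})
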