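#' Estimate the drift (functional connectivity) matrix
#'
#' For a stationary multivariate Ornstein-Uhlenbeck process the lagged
#' covariance obeys `C(tau) = expm(W tau) C(0)`. For lags small against the
#' relaxation time, `expm(W tau) ~ I + W tau`, giving the estimator
#'
#' \deqn{\hat W = (C(\tau) C(0)^{-1} - I) / \tau}
#'
#' `W[i, j]` is the coupling from channel `j` onto channel `i`, in 1/s. When
#' `C(0)` is rank-deficient its Moore-Penrose pseudo-inverse is used
#' (singular values below `1e-10` of the largest are truncated).
#'
#' @param rec a centered [mc_recording()].
#' @param lag_steps positive integer lag in samples (default 1; see
#'   [select_lag()]).
#' @return An object of class `conn_matrix`: list with `W` (N x N, 1/s),
#'   `channel_ids`, `lag_used` (seconds), `lag_steps`.
#' @export
estimate_connectivity <- function(rec, lag_steps = 1L) {
  stopifnot(inherits(rec, "mc_recording"))
  lag_steps <- as.integer(lag_steps)
  if (lag_steps < 1) stop("lag_steps must be >= 1")
  tau <- lag_steps * rec$dt
  C0 <- lagged_covariance(rec, 0L)$C
  if (max(abs(C0)) == 0) stop("degenerate input: zero covariance (all-zero data?)")
  Ct <- lagged_covariance(rec, lag_steps)$C
  s <- svd(C0)
  if (min(s$d) <= 1e-10 * max(s$d)) {
    C0inv <- pinv(C0)
  } else {
    C0inv <- chol2inv(chol(C0))
  }
  W <- (Ct %*% C0inv - diag(nrow(C0))) / tau
  dimnames(W) <- list(rec$channel_ids, rec$channel_ids)
  structure(list(W = W, channel_ids = rec$channel_ids,
                 lag_used = tau, lag_steps = lag_steps),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  st <- stability_spectrum(x)
  cat(sprintf("<conn_matrix> %d x %d drift operator (1/s), lag %g s, max Re(lambda) = %.4g (%s)\n",
              nrow(x$W), ncol(x$W), x$lag_used, st$max_real_part,
              if (st$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Select the fitting lag by minimal residual-noise trace
#'
#' Fits the model at each candidate lag and returns the lag whose empirical
#' noise covariance has the smallest trace, i.e. the lag minimising the mean
#' quadratic model error. Ties break toward the smallest lag. On data
#' resembling the model at 625 Hz the minimum sits at the smallest lag
#' available (one sample).
#'
#' @param rec a centered [mc_recording()].
#' @param candidate_lag_steps integer vector of candidate lags (samples),
#'   each `>= 1` and `<= T - 2`. Default `1:8`.
#' @return The selected lag (integer, samples), with attribute `"traces"`
#'   giving the residual-covariance trace per candidate.
#' @export
select_lag <- function(rec, candidate_lag_steps = 1:8) {
  stopifnot(inherits(rec, "mc_recording"))
  cand <- as.integer(candidate_lag_steps)
  if (length(cand) == 0) stop("candidate lag list is empty")
  if (any(cand < 1) || any(cand > ncol(rec$data) - 2))
    stop("candidate lags must lie in [1, T - 2]")
  cand <- sort(unique(cand))   # ascending, so which.min ties go to smallest lag
  traces <- vapply(cand, function(l) {
    W <- estimate_connectivity(rec, l)
    nm <- extract_residuals(rec, W, l)
    sum(diag(empirical_noise_covariance(nm, l, rec$dt)))
  }, numeric(1))
  structure(cand[which.min(traces)], traces = setNames(traces, cand))
}

#' Extract background-noise residuals
#'
#' Computes the forward-difference derivative of the signals and subtracts
#' the fitted drift: `r(t) = (x(t + tau) - x(t)) / tau - W x(t)`. The
#' residual traces are the reconstructed background noise driving the system.
#'
#' @param rec a centered [mc_recording()].
#' @param W a `conn_matrix` (or plain N x N matrix) matching `rec`.
#' @param lag_steps lag in samples used for the derivative (defaults to the
#'   lag stored in `W`).
#' @return An object of class `noise_model` with `residuals`
#'   (N x (T - lag_steps)), `dt`, `lag_steps`, `channel_ids`. The covariance
#'   slots `Q_empirical`, `Q_theoretical`, `agreement` are filled by
#'   [fit_subject()] or manually.
#' @export
extract_residuals <- function(rec, W, lag_steps = NULL) {
  stopifnot(inherits(rec, "mc_recording"))
  if (inherits(W, "conn_matrix")) {
    if (is.null(lag_steps)) lag_steps <- W$lag_steps
    W <- W$W
  }
  if (is.null(lag_steps)) stop("lag_steps required when W is a plain matrix")
  lag_steps <- as.integer(lag_steps)
  if (!all(dim(W) == nrow(rec$data)))
    stop("W dimensions do not match the recording")
  tau <- lag_steps * rec$dt
  T <- ncol(rec$data)
  X <- rec$data[, 1:(T - lag_steps), drop = FALSE]
  Xf <- rec$data[, (1 + lag_steps):T, drop = FALSE]
  R <- (Xf - X) / tau - W %*% X
  rownames(R) <- rec$channel_ids
  structure(list(residuals = R, dt = rec$dt, lag_steps = lag_steps,
                 channel_ids = rec$channel_ids,
                 Q_empirical = NULL, Q_theoretical = NULL, agreement = NA_real_),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d channels x %d residual samples",
              nrow(x$residuals), ncol(x$residuals)))
  if (!is.null(x$Q_empirical))
    cat(sprintf("; Q_E/Q_T agreement r = %.4f", x$agreement))
  cat("\n")
  invisible(x)
}

#' Empirical noise covariance
#'
#' Sample covariance of the residual traces, scaled by the lag `tau` so that
#' it matches the continuous-time diffusion convention
#' `<xi(t) xi(t')'> = Q delta(t - t')` and is directly comparable with the
#' theoretical covariance from the stationary identity.
#'
#' @param noise a `noise_model` from [extract_residuals()].
#' @param lag_steps,dt lag (samples) and sampling interval (s); default to
#'   the values stored in `noise`.
#' @return Symmetric N x N matrix `Q_E`.
#' @export
empirical_noise_covariance <- function(noise, lag_steps = noise$lag_steps,
                                       dt = noise$dt) {
  stopifnot(inherits(noise, "noise_model"))
  if (ncol(noise$residuals) < 2) stop("need at least 2 residual samples")
  tau <- lag_steps * dt
  R <- noise$residuals - rowMeans(noise$residuals)
  Q <- tau * tcrossprod(R) / (ncol(R) - 1)
  dimnames(Q) <- list(noise$channel_ids, noise$channel_ids)
  (Q + t(Q)) / 2
}

#' Theoretical noise covariance from the stationary identity
#'
#' For a stationary Ornstein-Uhlenbeck process the diffusion matrix is tied
#' to the drift and the zero-lag signal covariance by the Lyapunov relation
#' `W C0 + C0 W' + Q = 0`, i.e. `Q_T = -(W C0 + C0 W')`. Symmetric by
#' construction. A warning (not an error) is raised when `W` is not stable,
#' since the stationary identity is then only formal.
#'
#' @param W a `conn_matrix` or plain N x N matrix (1/s).
#' @param C0 a `lagged_cov` at lag 0 or plain symmetric N x N matrix.
#' @return Symmetric N x N matrix `Q_T`.
#' @export
theoretical_noise_covariance <- function(W, C0) {
  if (inherits(W, "conn_matrix")) W <- W$W
  if (inherits(C0, "lagged_cov")) C0 <- C0$C
  if (!all(dim(W) == dim(C0))) stop("W and C0 dimensions differ")
  C0 <- sym_check(C0, what = "C0")
  if (max(Re(eigen(W, only.values = TRUE)$values)) >= 0)
    warning("W is not stable; the stationary identity is only formal")
  Q <- -(W %*% C0 + C0 %*% t(W))
  (Q + t(Q)) / 2
}

#' Agreement between empirical and theoretical noise covariances
#'
#' Pearson correlation over all N^2 corresponding entries. Values close to 1
#' validate the linear stochastic model: the noise covariance predicted from
#' the fitted drift matches the one measured from the residuals.
#'
#' @param Q_E,Q_T same-dimension matrices.
#' @return Correlation in `[-1, 1]`, or `NaN` (flagged via attribute
#'   `"degenerate"`) when either matrix is constant.
#' @export
noise_agreement <- function(Q_E, Q_T) {
  if (!all(dim(Q_E) == dim(Q_T))) stop("dimension mismatch")
  if (sd(Q_E) == 0 || sd(Q_T) == 0)
    return(structure(NaN, degenerate = TRUE))
  cor(as.vector(Q_E), as.vector(Q_T))
}

#' Linear stability analysis of a drift matrix
#'
#' The fitted model is a valid description of resting-state dynamics only if
#' all eigenvalues of `W` have negative real parts; the largest real part
#' sets the slowest relaxation rate. A non-negative maximum flags a linearly
#' unstable (runaway, "epileptic") operator.
#'
#' @param W a `conn_matrix` or plain square matrix.
#' @return List of class `stability_report`: `eigenvalues` (complex),
#'   `max_real_part` (1/s), `stable` (logical).
#' @export
stability_spectrum <- function(W) {
  if (inherits(W, "conn_matrix")) W <- W$W
  if (nrow(W) != ncol(W)) stop("W must be square")
  ev <- eigen(W, only.values = TRUE)$values
  mrp <- max(Re(ev))
  structure(list(eigenvalues = ev, max_real_part = mrp, stable = mrp < 0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> max Re(lambda) = %.5g 1/s: %s\n",
              x$max_real_part, if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Residual diagnostics: Gaussianity and whiteness
#'
#' If the linear stochastic model is adequate, the extracted residuals should
#' be Gaussian and temporally white. Reports per-channel skewness, excess
#' kurtosis and a moment-based (Jarque-Bera) normality p-value, plus the
#' autocorrelogram up to `max_lag` and a whiteness score: the maximum
#' absolute autocorrelation over channels and nonzero lags.
#'
#' @param noise a `noise_model`.
#' @param max_lag maximum autocorrelation lag (samples), default 20.
#' @return List of class `residual_diagnostics` with `skewness`, `kurtosis`,
#'   `normality_p` (per channel), `autocorrelation` (channels x (max_lag+1),
#'   lag 0 first), `whiteness_score`.
#' @export
residual_diagnostics <- function(noise, max_lag = 20L) {
  stopifnot(inherits(noise, "noise_model"))
  R <- noise$residuals
  T <- ncol(R)
  if (T < 30) stop("need at least 30 residual samples for diagnostics")
  max_lag <- min(as.integer(max_lag), T - 2L)
  skew <- apply(R, 1, function(x) {
    x <- x - mean(x); mean(x^3) / mean(x^2)^1.5
  })
  kurt <- apply(R, 1, function(x) {
    x <- x - mean(x); mean(x^4) / mean(x^2)^2 - 3
  })
  jb <- T / 6 * (skew^2 + kurt^2 / 4)
  p <- pchisq(jb, df = 2, lower.tail = FALSE)
  ac <- t(apply(R, 1, function(x)
    as.vector(acf(x, lag.max = max_lag, plot = FALSE)$acf)))
  colnames(ac) <- paste0("lag", 0:max_lag)
  rownames(ac) <- noise$channel_ids
  white <- max(abs(ac[, -1, drop = FALSE]))
  structure(list(skewness = skew, kurtosis = kurt, normality_p = p,
                 autocorrelation = ac, whiteness_score = white,
                 n_samples = T),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<residual_diagnostics> %d samples; |skewness| <= %.3f; whiteness score %.4f (4/sqrt(T) = %.4f)\n",
    x$n_samples, max(abs(x$skewness)), x$whiteness_score, 4 / sqrt(x$n_samples)))
  invisible(x)
}

#' Fit the full stochastic model to one recording
#'
#' Convenience wrapper running the whole per-subject pipeline: centering,
#' drift estimation, residual extraction, empirical and theoretical noise
#' covariances, their agreement, and the stability spectrum.
#'
#' @param rec an [mc_recording()].
#' @param lag_steps fitting lag in samples (default 1).
#' @param select_from optional integer vector; when given, the lag is chosen
#'   by [select_lag()] over these candidates and `lag_steps` is ignored.
#' @return List of class `ou_fit` with `W` (`conn_matrix`), `noise`
#'   (`noise_model` with both Q matrices and `agreement` filled), `C0`,
#'   `stability`.
#' @export
fit_subject <- function(rec, lag_steps = 1L, select_from = NULL) {
  rec <- center_signals(rec)
  if (!is.null(select_from)) lag_steps <- as.integer(select_lag(rec, select_from))
  W <- estimate_connectivity(rec, lag_steps)
  nm <- extract_residuals(rec, W)
  nm$Q_empirical <- empirical_noise_covariance(nm)
  C0 <- lagged_covariance(rec, 0L)
  nm$Q_theoretical <- suppressWarnings(theoretical_noise_covariance(W, C0))
  nm$agreement <- noise_agreement(nm$Q_empirical, nm$Q_theoretical)
  structure(list(W = W, noise = nm, C0 = C0,
                 stability = stability_spectrum(W)),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  print(x$W)
  print(x$noise)
  invisible(x)
}
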