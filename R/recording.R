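#' Multichannel recording container
#'
#' Bundles a channels x samples signal block with its sampling interval and
#' channel identifiers. This is the basic input object of the package: one
#' resting-state recording epoch per subject, signal values interpreted
#' relative to baseline.
#'
#' @param data numeric matrix, N channels x T samples.
#' @param dt sampling interval in seconds (e.g. 1/625 for a 625 Hz system).
#' @param channel_ids character vector of length N; defaults to existing row
#'   names or `ch001, ch002, ...`.
#' @return An object of class `mc_recording`: a list with elements `data`,
#'   `dt`, `channel_ids`.
#' @examples
#' rec <- mc_recording(matrix(rnorm(20), 2, 10), dt = 1/625)
#' rec
#' @export
mc_recording <- function(data, dt, channel_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (nrow(data) < 2) stop("a recording needs at least 2 channels")
  if (ncol(data) < 3) stop("a recording needs at least 3 samples")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a positive scalar (seconds)")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids))
      channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop("channel_ids length must match the number of rows")
  if (anyDuplicated(channel_ids)) stop("channel ids must be unique")
  rownames(data) <- channel_ids
  structure(list(data = data, dt = dt, channel_ids = channel_ids),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples, dt = %g s (%.4g s)\n",
              nrow(x$data), ncol(x$data), x$dt, ncol(x$data) * x$dt))
  invisible(x)
}

#' @export
dim.mc_recording <- function(x) dim(x$data)

#' Remove the temporal mean of every channel
#'
#' The model describes activity as fluctuations about baseline, so each
#' channel is centered to zero temporal mean before any covariance is taken.
#'
#' @param rec an [mc_recording()].
#' @return The centered recording (idempotent).
#' @export
center_signals <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Project out leading principal components (artifact removal)
#'
#' Eye blinks and movement artifacts ride on many channels at high amplitude
#' and dominate the first few principal components of the channels x samples
#' block; projecting out the `k` leading components removes them while
#' leaving baseline fluctuations largely intact.
#'
#' @param rec an [mc_recording()].
#' @param k number of leading components to remove, `0 <= k < N`.
#' @return The cleaned recording (centered as a side effect of the PCA).
#' @export
remove_artifact_components <- function(rec, k) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- nrow(rec$data)
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < number of channels")
  rec <- center_signals(rec)
  if (k == 0) return(rec)
  # principal directions across channels: eigenvectors of the N x N covariance
  e <- eigen(tcrossprod(rec$data) / (ncol(rec$data) - 1), symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  rec$data <- rec$data - U %*% (t(U) %*% rec$data)
  rownames(rec$data) <- rec$channel_ids
  rec
}

#' Time-lagged covariance of a centered recording
#'
#' Computes `C(tau)` with the future-times-past orientation
#' `C_ij(tau) = < x_i(t + tau) x_j(t) >`, averaging over the `T - lag`
#' overlapping samples with divisor `T - lag - 1`. With this orientation a
#' stationary Ornstein-Uhlenbeck process satisfies
#' `C(tau) = expm(W tau) C(0)`, the identity the drift estimator relies on.
#'
#' @param rec an [mc_recording()] (signals should be centered).
#' @param lag_steps integer lag in samples, `0 <= lag_steps <= T - 2`.
#' @return A list of class `lagged_cov` with `C` (N x N), `lag` (seconds) and
#'   `lag_steps`.
#' @export
lagged_covariance <- function(rec, lag_steps = 0L) {
  stopifnot(inherits(rec, "mc_recording"))
  lag_steps <- as.integer(lag_steps)
  T <- ncol(rec$data)
  if (lag_steps < 0 || lag_steps > T - 2)
    stop("lag_steps must be between 0 and T - 2")
  X <- rec$data
  n_eff <- T - lag_steps
  fut <- X[, (1 + lag_steps):T, drop = FALSE]
  pst <- X[, 1:n_eff, drop = FALSE]
  C <- tcrossprod(fut, pst) / (n_eff - 1)
  if (lag_steps == 0L) C <- (C + t(C)) / 2
  dimnames(C) <- list(rec$channel_ids, rec$channel_ids)
  structure(list(C = C, lag = lag_steps * rec$dt, lag_steps = lag_steps),
            class = "lagged_cov")
}
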