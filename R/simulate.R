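#' Synthetic sensor layout
#'
#' Builds a layout emulating a whole-head sensor grid: `n` points spread
#' quasi-uniformly (Fibonacci lattice) over a spherical cap covering the
#' upper part of a head-sized sphere, plus their stereographic projection
#' onto a planar disc. Default 141 sensors on a 9 cm sphere, matching the
#' channel count retained in typical whole-head recordings.
#'
#' @param n number of sensors (default 141).
#' @param radius head-sphere radius in meters (default 0.09).
#' @param cap_fraction fraction of the sphere's polar angle covered by the
#'   cap (default 0.5: the upper hemisphere, projecting onto a disc of
#'   radius `2 * radius`).
#' @return A `data.frame` of class `sensor_layout` with columns
#'   `id, x, y, z` (meters, 3-D) and `px, py` (projected 2-D).
#' @export
synthetic_layout <- function(n = 141, radius = 0.09, cap_fraction = 0.5) {
  stopifnot(n >= 4, radius > 0, cap_fraction > 0, cap_fraction <= 1)
  i <- seq_len(n)
  # Fibonacci lattice on the cap z/R in [cos(pi*cap_fraction), 1]
  zmin <- cos(pi * cap_fraction)
  z <- 1 - (i - 0.5) / n * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pos <- data.frame(id = sprintf("s%03d", i),
                    x = radius * r_xy * cos(theta),
                    y = radius * r_xy * sin(theta),
                    z = radius * z)
  p2 <- stereographic_projection(as.matrix(pos[, c("x", "y", "z")]),
                                 center = c(0, 0, 0), radius = radius)
  pos$px <- p2[, 1]
  pos$py <- p2[, 2]
  class(pos) <- c("sensor_layout", "data.frame")
  pos
}

#' Random stable drift (connectivity) matrix
#'
#' Draws a sparse random matrix with mixed-sign Gaussian couplings and shifts
#' its diagonal so the largest real part of the spectrum equals
#' `target_max_real_part` exactly (within numerical precision). This mimics
#' fitted resting-state operators: stable, dissipating perturbations on a
#' sub-second time scale. By default the couplings are skew-dominant
#' (`skew_frac = 0.95`): the drift then behaves as a set of damped
#' oscillators (eigenfrequencies up to a few Hz at the default coupling
#' scale), emulating the rhythmic character of resting-state recordings.
#' Skew-dominant coupling also keeps every mode of the stationary process
#' comparably excited, which is what makes the drift identifiable from a
#' 30 s record.
#'
#' @param n number of nodes (>= 2).
#' @param target_max_real_part desired max real eigenvalue part, 1/s, < 0
#'   (default -2.5: relaxation time 0.4 s, under the sub-second bound).
#' @param density fraction of nonzero off-diagonal couplings in `[0, 1]`.
#' @param seed integer seed.
#' @param coupling_sd standard deviation of nonzero raw couplings before the
#'   symmetry split and spectral shift (1/s). Default `120 / n`: mean-field
#'   input normalization, so each node receives an O(1) total drive however
#'   fine the sensor grid, keeping relaxation and oscillation scales
#'   N-independent and the small-lag premise of the estimator valid.
#' @param skew_frac weight of the antisymmetric (oscillatory) component of
#'   the couplings, in `[0, 1]`; the symmetric component gets `1 - skew_frac`.
#' @return A `conn_matrix` with `lag_used = NA`.
#' @export
random_stable_connectivity <- function(n, target_max_real_part = -2.5,
                                       density = 0.4, seed = 1,
                                       coupling_sd = 120 / n, skew_frac = 0.95) {
  if (n < 2) stop("need n >= 2 nodes")
  if (target_max_real_part >= 0) stop("target max real part must be negative")
  set.seed(seed)
  M <- matrix(0, n, n)
  off <- which(row(M) != col(M))
  nz <- off[runif(length(off)) < density]
  M[nz] <- rnorm(length(nz), sd = coupling_sd)
  W <- skew_frac * (M - t(M)) / 2 + (1 - skew_frac) * (M + t(M)) / 2
  shift <- max(Re(eigen(W, only.values = TRUE)$values))
  W <- W + diag(target_max_real_part - shift, n)
  ids <- sprintf("s%03d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(W = W, channel_ids = ids, lag_used = NA_real_,
                 lag_steps = NA_integer_),
            class = "conn_matrix")
}

#' Spatially correlated noise covariance over a layout
#'
#' Squared-exponential kernel on 2-D sensor distances:
#' `Q_ij = variance * exp(-d_ij^2 / (2 l^2)) + ridge * variance * [i == j]`.
#' Short correlation lengths give patchy, near-diagonal noise; lengths beyond
#' the layout diameter give near-rank-1, globally coherent noise. The ridge
#' keeps the matrix positive definite.
#'
#' @param layout a `sensor_layout` (columns `px, py` used) or a 2-column
#'   coordinate matrix.
#' @param correlation_length kernel length scale, in the layout's units (> 0).
#' @param variance per-sensor noise variance (kernel sill), default 1.
#' @param ridge relative diagonal ridge, default 1e-3.
#' @return Symmetric positive-definite N x N matrix.
#' @export
spatial_noise_covariance <- function(layout, correlation_length,
                                     variance = 1, ridge = 1e-3) {
  if (correlation_length <= 0) stop("correlation_length must be > 0")
  P <- layout_coords2d(layout)
  d2 <- as.matrix(stats::dist(P))^2
  # coincident sensors simply get full correlation (d = 0); the ridge keeps
  # the matrix non-singular in that case.
  Q <- variance * exp(-d2 / (2 * correlation_length^2)) +
    diag(ridge * variance, nrow(P))
  if (!is.null(rownames(P))) dimnames(Q) <- list(rownames(P), rownames(P))
  Q
}

layout_coords2d <- function(layout) {
  if (inherits(layout, "sensor_layout") ||
      (is.data.frame(layout) && all(c("px", "py") %in% names(layout)))) {
    P <- as.matrix(layout[, c("px", "py")])
    rownames(P) <- layout$id
  } else {
    P <- as.matrix(layout)
    if (ncol(P) != 2) stop("layout must have 2-D coordinates")
  }
  P
}

layout_coords3d <- function(layout) {
  if (is.data.frame(layout) && all(c("x", "y", "z") %in% names(layout))) {
    P <- as.matrix(layout[, c("x", "y", "z")])
    rownames(P) <- layout$id
  } else {
    P <- as.matrix(layout)
    if (ncol(P) != 3) stop("layout must have 3-D coordinates")
  }
  P
}

#' Simulate a stationary Ornstein-Uhlenbeck recording
#'
#' Generates `x' = W x + xi` with white Gaussian noise of spatial covariance
#' `Q` (continuous-time convention `<xi(t) xi(t')'> = Q delta(t - t')`).
#'
#' The `"exact"` scheme samples the discretely observed process without
#' discretisation error: `x_{t+1} = A x_t + eta` with `A = expm(W dt)` and
#' `Cov(eta) = C - A C A'`, where `C` solves the stationary Lyapunov equation
#' `W C + C W' + Q = 0`; the initial state is drawn from the stationary law,
#' so the trajectory is stationary from the first sample. The `"euler"`
#' scheme is the Euler-Maruyama discretisation
#' `x_{t+1} = x_t + dt W x_t + sqrt(dt) L z`, `L L' = Q`, kept for
#' convergence checks.
#'
#' @param W drift: `conn_matrix` or plain stable N x N matrix (1/s).
#' @param Q diffusion: symmetric PSD N x N matrix.
#' @param dt sampling interval (s), default 1/625.
#' @param duration record length (s); `duration / dt >= 10` required.
#' @param scheme `"exact"` (default) or `"euler"`.
#' @param seed integer seed.
#' @param x0 optional initial state; defaults to a stationary draw (exact)
#'   or zeros (euler).
#' @return An [mc_recording()].
#' @export
simulate_moup <- function(W, Q, dt = 1 / 625, duration = 30,
                          scheme = c("exact", "euler"), seed = 1, x0 = NULL) {
  if (inherits(W, "conn_matrix")) { ids <- W$channel_ids; W <- W$W }
  else ids <- rownames(W)
  scheme <- match.arg(scheme)
  n <- nrow(W)
  if (!all(dim(Q) == n)) stop("W and Q dimensions differ")
  Q <- sym_check(Q, what = "Q")
  T <- floor(duration / dt)
  if (T < 10) stop("duration/dt must be at least 10")
  set.seed(seed)
  X <- matrix(0, n, T)
  if (scheme == "exact") {
    if (max(Re(eigen(W, only.values = TRUE)$values)) >= 0)
      stop("exact scheme requires a stable W (stationary law must exist)")
    A <- expm_eig(W * dt)
    C <- lyapunov_solve(W, Q)
    S <- C - A %*% C %*% t(A)
    L <- psd_sqrt(S)
    x <- if (is.null(x0)) psd_sqrt(C) %*% rnorm(n) else as.numeric(x0)
    E <- L %*% matrix(rnorm(n * T), n, T)
    for (t in seq_len(T)) {
      x <- A %*% x + E[, t]
      X[, t] <- x
    }
  } else {
    L <- psd_sqrt(Q)
    x <- if (is.null(x0)) rep(0, n) else as.numeric(x0)
    E <- sqrt(dt) * (L %*% matrix(rnorm(n * T), n, T))
    Adt <- diag(n) + dt * W
    for (t in seq_len(T)) {
      x <- Adt %*% x + E[, t]
      X[, t] <- x
    }
  }
  mc_recording(X, dt = dt, channel_ids = ids)
}

#' Cohort specification for the synthetic two-group generator
#'
#' Describes the "stated world" of a simulated case/control study: a shared
#' base drift matrix, a list of planted connection differences applied to the
#' patient group, group-specific noise correlation lengths over a shared
#' layout, and subject-level jitter creating within-group spread.
#'
#' @param n_control,n_patient group sizes (defaults 10 and 9, the design of
#'   a small case/control study).
#' @param layout a `sensor_layout`; default [synthetic_layout()] with
#'   `n_channels` sensors.
#' @param n_channels number of channels when `layout` is NULL (default 141).
#' @param base_W base drift; default [random_stable_connectivity()] on the
#'   layout (max real part -2.5/s, oscillatory couplings).
#' @param deltas data.frame with columns `i, j, delta` (1/s): additive
#'   perturbations to `W[i, j]` in the patient group. Default one planted
#'   increase of +4/s (about a third of the typical coupling magnitude,
#'   large against both subject jitter and estimation noise).
#' @param ell_control,ell_patient noise correlation lengths (meters, on the
#'   projected layout): default 0.06 control vs 0.18 patient, emulating
#'   patchy vs spatially extended background noise.
#' @param noise_variance kernel variance of Q (default 1).
#' @param jitter_sd sd of i.i.d. Gaussian jitter added to the nonzero entries
#'   of each subject's drift (1/s), default 0.5: visible within-group spread,
#'   comparable to the drift-estimation noise at 30 s.
#' @param dt,duration sampling interval and record length (defaults 1/625 s,
#'   30 s).
#' @param seed master seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 10, n_patient = 9,
                        layout = NULL, n_channels = 141,
                        base_W = NULL,
                        deltas = data.frame(i = 2, j = 1, delta = 4),
                        ell_control = 0.06, ell_patient = 0.18,
                        noise_variance = 1,
                        jitter_sd = 0.5,
                        dt = 1 / 625, duration = 30, seed = 1) {
  if (is.null(layout)) layout <- synthetic_layout(n_channels)
  if (is.null(base_W))
    base_W <- random_stable_connectivity(nrow(layout),
                                         seed = derive_seed(seed, 1))
  if (inherits(base_W, "conn_matrix")) base_W <- base_W$W
  stopifnot(nrow(base_W) == nrow(layout))
  if (n_control < 1 || n_patient < 1) stop("both groups need >= 1 subject")
  structure(list(n_control = n_control, n_patient = n_patient,
                 layout = layout, base_W = base_W, deltas = deltas,
                 ell_control = ell_control, ell_patient = ell_patient,
                 noise_variance = noise_variance, jitter_sd = jitter_sd,
                 dt = dt, duration = duration, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject drift matrices (base + planted group deltas + subject
#' jitter, resampled up to 100 times if jitter destabilises the matrix),
#' builds each group's noise covariance from its correlation length, and
#' simulates one recording per subject with the exact scheme. The returned
#' dataset records the ground truth so downstream recovery can be asserted.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `cohort` with `subjects` (list of `id`, `group`,
#'   `recording`, `W_true`), `groups` (factor), `layout`, `dt`,
#'   `ground_truth` (base W, deltas, correlation lengths, seed).
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lay <- spec$layout
  n <- nrow(lay)
  W_pat <- spec$base_W
  if (nrow(spec$deltas) > 0) {
    for (k in seq_len(nrow(spec$deltas)))
      W_pat[spec$deltas$i[k], spec$deltas$j[k]] <-
        W_pat[spec$deltas$i[k], spec$deltas$j[k]] + spec$deltas$delta[k]
    if (max(Re(eigen(W_pat, only.values = TRUE)$values)) >= 0)
      stop("planted deltas destabilise the patient-group drift; ",
           "reduce delta or pick another connection")
  }
  Qc <- spatial_noise_covariance(lay, spec$ell_control, spec$noise_variance)
  Qp <- spatial_noise_covariance(lay, spec$ell_patient, spec$noise_variance)
  make_subject <- function(idx, group) {
    base <- if (group == "control") spec$base_W else W_pat
    Q <- if (group == "control") Qc else Qp
    sseed <- derive_seed(spec$seed, 1000 + idx)
    set.seed(sseed)
    for (attempt in 1:100) {
      Wj <- base
      nz <- which(base != 0)
      Wj[nz] <- Wj[nz] + rnorm(length(nz), sd = spec$jitter_sd)
      if (max(Re(eigen(Wj, only.values = TRUE)$values)) < 0) break
      if (attempt == 100) stop("jittered W unstable after 100 attempts")
    }
    rec <- simulate_moup(Wj, Q, dt = spec$dt, duration = spec$duration,
                         scheme = "exact", seed = derive_seed(sseed, 7))
    rec$channel_ids <- lay$id
    rownames(rec$data) <- lay$id
    list(id = sprintf("%s%02d", substr(group, 1, 3), idx),
         group = group, recording = rec, W_true = Wj)
  }
  subs <- c(lapply(seq_len(spec$n_control), make_subject, group = "control"),
            lapply(seq_len(spec$n_patient) + spec$n_control, make_subject,
                   group = "patient"))
  structure(list(subjects = subs,
                 groups = factor(vapply(subs, `[[`, "", "group"),
                                 levels = c("control", "patient")),
                 layout = lay, dt = spec$dt,
                 ground_truth = list(base_W = spec$base_W,
                                     deltas = spec$deltas,
                                     ell_control = spec$ell_control,
                                     ell_patient = spec$ell_patient,
                                     jitter_sd = spec$jitter_sd,
                                     seed = spec$seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d channels, dt = %g s\n",
              length(x$subjects),
              paste(table(x$groups), names(table(x$groups)), collapse = " + "),
              nrow(x$layout), x$dt))
  invisible(x)
}

#' Fit the stochastic model to every subject of a cohort
#'
#' @param cohort a `cohort` (from [synthesize_cohort()] or [load_cohort()]).
#' @param lag_steps fitting lag (samples), default 1.
#' @return The cohort with a per-subject `fit` element (`ou_fit`) added.
#' @export
fit_cohort <- function(cohort, lag_steps = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$subjects <- lapply(cohort$subjects, function(s) {
    s$fit <- fit_subject(s$recording, lag_steps = lag_steps)
    s
  })
  cohort
}
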