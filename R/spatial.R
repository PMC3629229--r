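#' Stereographic projection of sensor positions onto a plane
#'
#' Fits a sphere to the sensor cloud by linear least squares (unless center
#' and radius are supplied), then maps each sensor from the inferior pole
#' (the point of the sphere with minimal z) onto the plane tangent at the
#' superior pole. The superior pole maps to the origin and the equator to a
#' circle of radius equal to the sphere diameter; the map is conformal, so
#' local circularity of the grid is preserved.
#'
#' @param positions3D N x 3 matrix of sensor coordinates (meters).
#' @param center,radius optional sphere parameters; fitted when omitted.
#' @param scale multiplicative scale of the planar coordinates (default 1).
#' @return N x 2 matrix of projected coordinates. Attributes `center` and
#'   `radius` carry the sphere used.
#' @export
stereographic_projection <- function(positions3D, center = NULL, radius = NULL,
                                     scale = 1) {
  P <- layout_coords3d(positions3D)
  if (is.null(center) || is.null(radius)) {
    fit <- fit_sphere(P)
    center <- fit$center; radius <- fit$radius
  }
  Pc <- sweep(P, 2, center)
  r <- sqrt(rowSums(Pc^2))
  Pu <- Pc / r * radius                 # radial projection onto the sphere
  z <- Pu[, 3]
  if (any(z <= -radius * (1 - 1e-9)))
    stop("a sensor sits at the projection pole")
  t <- 2 * radius / (z + radius)
  out <- scale * cbind(t * Pu[, 1], t * Pu[, 2])
  rownames(out) <- rownames(P)
  colnames(out) <- c("px", "py")
  attr(out, "center") <- center
  attr(out, "radius") <- radius
  out
}

# Least-squares sphere fit: |p|^2 = 2 c . p + (R^2 - |c|^2) is linear in
# (c, R^2 - |c|^2).
fit_sphere <- function(P) {
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  radius <- sqrt(beta[4] + sum(center^2))
  list(center = center, radius = radius)
}

#' Dominant spatial pattern of the background noise
#'
#' Eigen-decomposes the (symmetric) noise covariance and returns the
#' eigenvalue-weighted average of its eigenvectors, weights normalized to
#' sum 1: `pattern = sum_k (lambda_k v_k) / sum_k lambda_k`. Each unit
#' eigenvector is first oriented so that its largest-magnitude component is
#' positive (the decomposition is otherwise sign-ambiguous). One value per
#' sensor; plotted on the layout it shows where the driving noise is
#' spatially coherent.
#'
#' @param Q symmetric N x N noise covariance.
#' @param tol relative tolerance for detecting (near-)degenerate leading
#'   eigenvalues (default `1e-8`).
#' @return Numeric vector of length N of class `spatial_pattern`, with
#'   attributes `weights` (normalized eigenvalues) and `degenerate` (TRUE
#'   when the spectrum has ties beyond `tol`, making the pattern
#'   non-informative).
#' @export
dominant_noise_pattern <- function(Q, tol = 1e-8) {
  Q <- sym_check(Q, what = "Q")
  e <- eigen(Q, symmetric = TRUE)
  V <- e$vectors
  # fix signs: largest-|component| positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  lam <- e$values
  if (sum(lam) <= 0) stop("Q has non-positive total variance")
  wts <- lam / sum(lam)
  pattern <- as.vector(V %*% wts)
  names(pattern) <- rownames(Q)
  degen <- any(abs(diff(lam)) < tol * max(abs(lam)))
  structure(pattern, weights = wts, degenerate = degen,
            class = "spatial_pattern")
}

#' @export
print.spatial_pattern <- function(x, ...) {
  cat(sprintf("<spatial_pattern> %d sensors, range [%.3g, %.3g]%s\n",
              length(x), min(x), max(x),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate spectrum]" else ""))
  invisible(x)
}

# Biharmonic-spline (Green's function r^2 (ln r - 1)) scattered-data
# interpolation in 2-D, augmented with an affine tail (1, x, y) under the
# usual orthogonality side conditions, so constant and planar fields are
# reproduced exactly. Returns predictions at `at` given values `y` at
# support points `P`.
biharmonic_interp <- function(P, y, at) {
  phi <- function(D) {
    G <- D^2 * (log(D) - 1)
    G[D == 0] <- 0
    G
  }
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  if (any(D[upper.tri(D)] == 0)) stop("coincident sensors: singular interpolation")
  Pm <- cbind(1, P)
  A <- rbind(cbind(phi(D), Pm), cbind(t(Pm), matrix(0, 3, 3)))
  coef <- solve(A, c(y, numeric(3)))
  D2q <- outer(rowSums(at^2), rowSums(P^2), `+`) - 2 * at %*% t(P)
  Dq <- sqrt(pmax(D2q, 0))
  as.vector(phi(Dq) %*% coef[1:n] + cbind(1, at) %*% coef[n + (1:3)])
}

#' Spatial complexity of a sensor pattern
#'
#' Leave-one-out interpolation error: for each sensor, the pattern value is
#' predicted by a smooth biharmonic-spline interpolation fitted on all the
#' other sensors and evaluated at the held-out position; the statistic is
#' the root-mean-square of (value - prediction) over sensors. Patterns whose
#' values are well predicted by their neighbours (spatially extended
#' correlation) score low; patchy, heterogeneous patterns score high.
#' Homogeneous of degree 1 (`complexity(a X) = |a| complexity(X)`) and
#' exactly zero on constant and planar patterns (the interpolant carries an
#' affine tail), hence invariant to adding a constant.
#'
#' @param pattern numeric vector, one value per sensor.
#' @param layout a `sensor_layout` or N x 2 coordinate matrix (distinct
#'   points).
#' @param k_neighbors optional: use only the `k` nearest sensors as
#'   interpolation support (default `NULL` = all other sensors).
#' @return Nonnegative scalar.
#' @export
spatial_complexity <- function(pattern, layout, k_neighbors = NULL) {
  P <- layout_coords2d(layout)
  x <- as.numeric(pattern)
  if (length(x) != nrow(P)) stop("pattern length does not match layout")
  if (nrow(P) < 4) stop("need at least 4 sensors")
  if (!all(is.finite(x))) stop("pattern contains non-finite values")
  n <- nrow(P)
  err <- vapply(seq_len(n), function(s) {
    idx <- setdiff(seq_len(n), s)
    if (!is.null(k_neighbors)) {
      d <- sqrt(rowSums(sweep(P[idx, , drop = FALSE], 2, P[s, ])^2))
      idx <- idx[order(d)[seq_len(min(k_neighbors, length(idx)))]]
    }
    pred <- biharmonic_interp(P[idx, , drop = FALSE], x[idx],
                              P[s, , drop = FALSE])
    x[s] - pred
  }, numeric(1))
  sqrt(mean(err^2))
}

#' Cross-talk profile: signal covariance versus sensor distance
#'
#' Tabulates the zero-lag covariance of every unordered sensor pair against
#' the 3-D distance between the sensors, restricted to pairs closer than
#' `max_distance`, and fits a least-squares line. A large negative Pearson
#' `r` at short range is the signature of shared sources / sensor
#' cross-talk; comparing per-subject `r` values between groups (e.g. with
#' [ranksum_compare()]) checks that cross-talk cannot explain group
#' differences.
#'
#' @param C0 symmetric zero-lag covariance (`lagged_cov` or matrix).
#' @param layout a `sensor_layout` or N x 3 coordinate matrix.
#' @param max_distance pair-distance cutoff in meters (default 0.10).
#' @return List of class `crosstalk_profile`: `pairs` (data.frame with
#'   `i, j, distance, covariance`), `slope`, `intercept`, `r`.
#' @export
crosstalk_profile <- function(C0, layout, max_distance = 0.10) {
  if (inherits(C0, "lagged_cov")) C0 <- C0$C
  C0 <- sym_check(C0, what = "C0")
  P <- layout_coords3d(layout)
  if (nrow(P) != nrow(C0)) stop("layout does not match C0")
  D <- as.matrix(stats::dist(P))
  idx <- which(upper.tri(D) & D <= max_distance, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no sensor pairs within max_distance")
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   distance = D[idx], covariance = C0[idx])
  if (nrow(df) >= 2 && sd(df$distance) > 0 && sd(df$covariance) > 0) {
    fit <- stats::lm(covariance ~ distance, data = df)
    slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
    r <- cor(df$distance, df$covariance)
  } else {
    slope <- intercept <- r <- NA_real_
  }
  structure(list(pairs = df, slope = slope, intercept = intercept, r = r,
                 max_distance = max_distance),
            class = "crosstalk_profile")
}

#' @export
print.crosstalk_profile <- function(x, ...) {
  cat(sprintf("<crosstalk_profile> %d pairs within %.2f m; r = %.3f\n",
              nrow(x$pairs), x$max_distance, x$r))
  invisible(x)
}
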