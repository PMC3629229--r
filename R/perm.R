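#' Random permutation test for a difference of group means
#'
#' Pools the `n + m` values, repeatedly re-partitions them at random into
#' surrogate groups of sizes `n` and `m`, and builds the null distribution of
#' the difference of means. Returns the z-score of the observed difference
#' (observed difference divided by the null standard deviation, divisor
#' `n_perm - 1`), the left-tail p (fraction of the null at or below the
#' observed value) and a two-sided p (fraction of `|null| >= |observed|`).
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param n_perm number of random re-partitions (default 10000).
#' @param seed integer seed.
#' @return List of class `perm_test`: `observed_diff` (mean A - mean B),
#'   `z_score`, `p_left`, `p_two_sided`, `n_permutations`, `seed`,
#'   `degenerate` (TRUE when all pooled values are equal: z set to 0,
#'   two-sided p to 1).
#' @export
permutation_diff_test <- function(values_a, values_b, n_perm = 10000, seed = 1) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  pooled <- c(a, b)
  n <- length(a); m <- length(b); N <- n + m
  obs <- mean(a) - mean(b)
  if (max(pooled) == min(pooled)) {
    return(structure(list(observed_diff = obs, z_score = 0, p_left = 1,
                          p_two_sided = 1, n_permutations = n_perm,
                          seed = seed, degenerate = TRUE),
                     class = "perm_test"))
  }
  set.seed(seed)
  tot <- sum(pooled)
  null <- vapply(seq_len(n_perm), function(k) {
    sa <- sum(pooled[sample.int(N, n)])
    sa / n - (tot - sa) / m
  }, numeric(1))
  s <- sd(null)
  structure(list(observed_diff = obs,
                 z_score = if (s > 0) obs / s else 0,
                 p_left = mean(null <= obs),
                 p_two_sided = mean(abs(null) >= abs(obs)),
                 n_permutations = n_perm, seed = seed,
                 degenerate = s == 0),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> diff = %.4g, z = %.3f, two-sided p = %.4g (%d permutations)%s\n",
              x$observed_diff, x$z_score, x$p_two_sided, x$n_permutations,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Connection-wise group comparison with permutation z-scores
#'
#' For every ordered channel pair `(i, j)` collects the fitted coupling
#' `W[i, j]` across subjects of each group and runs an independent
#' [permutation_diff_test()] (patient minus control). Assembles:
#' `delta` (difference of group means), `zmap` (z-scores), the z-weighted
#' absolute change map `delta * z`, the relative change map
#' `delta / |mean control|` weighted by z (masked where the control-group
#' mean is below `1e-3` of the median absolute control mean), and per-node
#' input (row) and output (column) aggregates of the weighted maps.
#'
#' @param cohort a fitted `cohort` (see [fit_cohort()]); alternatively a list
#'   with `Ws` (list of N x N matrices) and `groups` (factor, first level =
#'   control/reference).
#' @param n_perm permutations per connection (default 10000; reduce for large
#'   N).
#' @param seed master seed; per-connection seeds are derived from it.
#' @return List of class `change_maps` with the maps above plus `p_two_sided`
#'   and the input/output aggregates.
#' @export
connectionwise_changes <- function(cohort, n_perm = 10000, seed = 1) {
  xs <- cohort_matrices(cohort, "W")
  groups <- cohort_groups(cohort)
  ctrl <- levels(groups)[1]
  Wc <- xs[groups == ctrl]
  Wp <- xs[groups != ctrl]
  if (length(Wc) == 0 || length(Wp) == 0) stop("both groups must be nonempty")
  N <- nrow(xs[[1]])
  Ac <- simplify2array(Wc); Ap <- simplify2array(Wp)
  delta <- apply(Ap, c(1, 2), mean) - apply(Ac, c(1, 2), mean)
  zmap <- pmat <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    pt <- permutation_diff_test(Ap[i, j, ], Ac[i, j, ], n_perm = n_perm,
                                seed = derive_seed(seed, (i - 1) * N + j))
    zmap[i, j] <- pt$z_score
    pmat[i, j] <- pt$p_two_sided
  }
  ctrl_mean <- apply(Ac, c(1, 2), mean)
  floor_val <- 1e-3 * median(abs(ctrl_mean))
  rel <- delta / abs(ctrl_mean)
  rel[abs(ctrl_mean) < floor_val] <- NA_real_
  weighted <- delta * zmap
  rel_weighted <- rel * zmap
  ids <- rownames(xs[[1]])
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(N))
  for (M in c("delta", "zmap", "pmat", "weighted", "rel", "rel_weighted")) {
    tmp <- get(M); dimnames(tmp) <- list(ids, ids); assign(M, tmp)
  }
  structure(list(delta = delta, zmap = zmap, p_two_sided = pmat,
                 weighted_abs = weighted, relative = rel,
                 weighted_rel = rel_weighted,
                 input_abs = rowMeans(weighted),
                 output_abs = colMeans(weighted),
                 input_rel = rowMeans(rel_weighted, na.rm = TRUE),
                 output_rel = colMeans(rel_weighted, na.rm = TRUE),
                 channel_ids = ids, n_perm = n_perm, seed = seed),
            class = "change_maps")
}

#' @export
print.change_maps <- function(x, ...) {
  cat(sprintf("<change_maps> %d x %d connections, %d permutations; max |z| = %.2f\n",
              nrow(x$zmap), ncol(x$zmap), x$n_perm, max(abs(x$zmap))))
  invisible(x)
}

#' Rank the dominant connectivity changes
#'
#' Returns the top-`k` directed pairs by absolute value of the z-weighted
#' change maps, for both absolute and relative weighting — the tabular data
#' behind an "arrow plot" of dominant changes. Self-loops are excluded
#' (arrows connect distinct sensors); ties break deterministically by
#' (row, column) index order; masked relative entries are skipped.
#'
#' @param maps a `change_maps` object.
#' @param k number of pairs to return, `0 <= k <= N^2 - N`.
#' @return List with `absolute` and `relative`, each a data.frame with
#'   columns `source, target, value` sorted by decreasing `|value|`.
#' @export
rank_changes <- function(maps, k = 10) {
  stopifnot(inherits(maps, "change_maps"))
  N <- nrow(maps$zmap)
  if (k > N^2 - N) stop("k exceeds the number of off-diagonal pairs")
  rank_one <- function(M) {
    idx <- which(row(M) != col(M) & is.finite(M), arr.ind = TRUE)
    v <- M[idx]
    o <- order(-abs(v), idx[, 1], idx[, 2])
    o <- head(o, k)
    data.frame(source = maps$channel_ids[idx[o, 2]],
               target = maps$channel_ids[idx[o, 1]],
               source_idx = idx[o, 2], target_idx = idx[o, 1],
               value = v[o], row.names = NULL)
  }
  list(absolute = rank_one(maps$weighted_abs),
       relative = rank_one(maps$weighted_rel))
}

#' Excitation/inhibition balance of a drift matrix
#'
#' Per node: `I+` and `I-` are the sums of positive and negative incoming
#' couplings (across each row), `O+` and `O-` the same across columns
#' (outgoing). A balanced network shows strong absolute correlation between
#' `I+` and `I-` (each node receives as much functional excitation as
#' inhibition) and between `O+` and `O-`. All six pairwise absolute Pearson
#' correlations are reported; a correlation involving a zero-variance vector
#' is returned as `NA` (flagged).
#'
#' @param W a `conn_matrix` or plain square matrix.
#' @return List of class `balance_report` with vectors `I_plus, I_minus,
#'   O_plus, O_minus` and the named `correlations` vector.
#' @export
balance_analysis <- function(W) {
  if (inherits(W, "conn_matrix")) W <- W$W
  if (nrow(W) != ncol(W)) stop("W must be square")
  Ip <- rowSums(pmax(W, 0)); Im <- rowSums(pmin(W, 0))
  Op <- colSums(pmax(W, 0)); Om <- colSums(pmin(W, 0))
  acor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    abs(cor(u, v))
  }
  cors <- c("I+/I-" = acor(Ip, Im), "O+/O-" = acor(Op, Om),
            "I+/O+" = acor(Ip, Op), "I+/O-" = acor(Ip, Om),
            "I-/O+" = acor(Im, Op), "I-/O-" = acor(Im, Om))
  structure(list(I_plus = Ip, I_minus = Im, O_plus = Op, O_minus = Om,
                 correlations = cors),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> |correlations|:\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Midrank-tied rank-sum test: exact enumeration of all partitions when
#' `choose(n + m, n) <= 5000` (covers `n + m <= 12` even unbalanced),
#' otherwise the normal approximation with continuity correction and tie
#' correction.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @return List of class `ranksum` with `statistic` (rank sum of group A),
#'   `p_value` (two-sided), `method` ("exact" or "normal").
#' @export
ranksum_compare <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))   # midranks for ties
  Wobs <- sum(r[seq_len(n)])
  if (choose(N, n) <= 5000) {
    parts <- combn(N, n)
    sums <- colSums(matrix(r[parts], nrow = n))
    mu <- n * (N + 1) / 2
    p <- mean(abs(sums - mu) >= abs(Wobs - mu) - 1e-12)
    method <- "exact"
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (Wobs - mu - sign(Wobs - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = Wobs, p_value = min(p, 1), method = method),
            class = "ranksum")
}

#' @export
print.ranksum <- function(x, ...) {
  cat(sprintf("<ranksum> W = %g, two-sided p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}

# --- cohort accessors shared by the statistics and classification layers ----

cohort_matrices <- function(cohort, which = c("W", "Q")) {
  which <- match.arg(which)
  if (inherits(cohort, "cohort")) {
    lapply(cohort$subjects, function(s) {
      if (is.null(s$fit)) stop("subject ", s$id, " has no fit; run fit_cohort()")
      if (which == "W") s$fit$W$W else s$fit$noise$Q_empirical
    })
  } else if (is.list(cohort) && !is.null(cohort$Ws)) {
    cohort$Ws
  } else stop("unsupported cohort object")
}

cohort_groups <- function(cohort) {
  g <- cohort$groups
  if (is.null(g)) stop("cohort has no group labels")
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2) stop("exactly two group labels required")
  g
}
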