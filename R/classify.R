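#' Vectorize a square matrix into a feature row
#'
#' Row-major flattening: element `(i, j)` lands at position
#' `(i - 1) * N + j`. A 141 x 141 connectivity matrix becomes a vector of
#' 19881 features. [unvectorize_matrix()] inverts the operation.
#'
#' @param M square matrix.
#' @return Numeric vector of length `N^2`.
#' @export
vectorize_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  as.vector(t(M))
}

#' @rdname vectorize_matrix
#' @param v numeric vector of square length.
#' @export
unvectorize_matrix <- function(v) {
  n <- sqrt(length(v))
  if (n != round(n)) stop("length is not a perfect square")
  matrix(v, n, n, byrow = TRUE)
}

#' Build a feature set from a fitted cohort
#'
#' One row per subject: the vectorized drift matrix (`source = "W"`) or
#' empirical noise covariance (`source = "Q"`). Both feature types run
#' through identical downstream code; only the provenance tag differs.
#'
#' @param cohort a fitted `cohort`, or a list of square matrices plus a
#'   `groups` factor via arguments `matrices`/`groups`.
#' @param source `"W"` or `"Q"`.
#' @param matrices,groups alternative direct inputs.
#' @return List of class `feature_set`: `X` (subjects x features), `labels`
#'   (two-level factor; second level is the patient/positive class),
#'   `source`.
#' @export
feature_set <- function(cohort = NULL, source = c("W", "Q"),
                        matrices = NULL, groups = NULL) {
  source <- match.arg(source)
  if (!is.null(cohort)) {
    matrices <- cohort_matrices(cohort, source)
    groups <- cohort_groups(cohort)
  }
  if (is.null(matrices) || is.null(groups)) stop("need a cohort or matrices+groups")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two label values required")
  X <- do.call(rbind, lapply(matrices, vectorize_matrix))
  if (nrow(X) != length(groups)) stop("labels do not match subjects")
  structure(list(X = X, labels = groups, source = source),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d subjects x %d features (%s); groups: %s\n",
              nrow(x$X), ncol(x$X), x$source,
              paste(table(x$labels), levels(x$labels), collapse = " + ")))
  invisible(x)
}

#' Train a linear support-vector classifier
#'
#' Maximal-margin linear separator trained by a deterministic SMO-type
#' coordinate ascent on the dual problem. The soft-margin cost defaults to a
#' very large value, making the fit effectively hard-margin: with few
#' subjects in tens of thousands of dimensions the classes are linearly
#' separable and the decision function is the plane
#' `f(x) = sum_k a_k y_k <s_k, x> + b`. Features are used as-is (no
#' standardization).
#'
#' @param X subjects x features matrix.
#' @param y two-level factor or `+/-1` vector. The *first* factor level maps
#'   to `+1` (classified as group 1 when `f(x) > 0`).
#' @param cost soft-margin cost `C` (default `1e4`).
#' @param tol KKT tolerance (default `1e-6` of the data scale).
#' @param max_passes consecutive full passes without progress that stop the
#'   optimisation (default 3).
#' @param max_iter hard cap on total passes (default 300); on non-separable
#'   inputs the dual is cut off there, which is ample for the package's
#'   few-subject use case.
#' @return List of class `svm_model` with `alpha`, `support` (indices),
#'   `support_vectors`, `coef` (`alpha * y` on support), `b`, `w` (explicit
#'   normal vector), `levels`.
#' @export
svm_train <- function(X, y, cost = 1e4, tol = 1e-6, max_passes = 3,
                      max_iter = 300) {
  X <- as.matrix(X)
  lv <- NULL
  if (is.factor(y) || is.character(y)) {
    y <- droplevels(as.factor(y))
    if (nlevels(y) != 2) stop("need exactly two classes")
    lv <- levels(y)
    y <- ifelse(y == lv[1], 1, -1)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("single-class input: cannot train")
  n <- nrow(X)
  K <- tcrossprod(X)                      # linear kernel Gram matrix
  scale <- max(abs(K), 1)
  eps <- tol * scale
  alpha <- rep(0, n)
  b <- 0
  passes <- 0
  iter <- 0
  repeat {
    changed <- 0L
    f <- as.vector(K %*% (alpha * y)) + b
    E <- f - y
    for (i in seq_len(n)) {
      ri <- E[i] * y[i]
      if ((ri < -tol && alpha[i] < cost) || (ri > tol && alpha[i] > 0)) {
        j <- which.max(abs(E[i] - E))     # deterministic second choice
        if (j == i) next
        eta <- K[i, i] + K[j, j] - 2 * K[i, j]
        if (eta <= 1e-12 * scale) next
        aj_old <- alpha[j]; ai_old <- alpha[i]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(cost, cost + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - cost); H <- min(cost, ai_old + aj_old)
        }
        if (H - L < 1e-12) next
        aj <- aj_old + y[j] * (E[i] - E[j]) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-10 * (aj + aj_old + 1e-10)) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - E[i] - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - E[j] - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < cost) b1
             else if (aj > 0 && aj < cost) b2
             else (b1 + b2) / 2
        f <- as.vector(K %*% (alpha * y)) + b
        E <- f - y
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1 else 0
    iter <- iter + 1
    if (passes >= max_passes || iter >= max_iter) break
  }
  sv <- which(alpha > 1e-8 * max(alpha, 1e-12))
  w <- as.vector(t(X[sv, , drop = FALSE]) %*% (alpha[sv] * y[sv]))
  structure(list(alpha = alpha, support = sv,
                 support_vectors = X[sv, , drop = FALSE],
                 coef = alpha[sv] * y[sv], b = b, w = w, levels = lv),
            class = "svm_model")
}

#' @rdname svm_train
#' @param model an `svm_model`.
#' @param x a feature vector or matrix of rows to score.
#' @return `svm_decision`: signed decision value(s) `f(x)`;
#'   `svm_classify`: predicted label(s) (`f(x) > 0` means the first level).
#' @export
svm_decision <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.vector(x %*% model$w + model$b)
}

#' @rdname svm_train
#' @export
svm_classify <- function(model, x) {
  d <- svm_decision(model, x)
  if (is.null(model$levels)) return(ifelse(d > 0, 1, -1))
  factor(ifelse(d > 0, model$levels[1], model$levels[2]),
         levels = model$levels)
}

#' PCA projection of a feature set
#'
#' Mean-centered principal component analysis across subjects, used to
#' visualize group separation of the vectorized matrices in a few
#' dimensions.
#'
#' @param features a `feature_set` (or plain matrix).
#' @param n_components number of components (default 3).
#' @return List with `coordinates` (subjects x n_components),
#'   `explained_variance` (fractions), `labels` (if available).
#' @export
pca_projection <- function(features, n_components = 3) {
  X <- if (inherits(features, "feature_set")) features$X else as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 subjects")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds min(subjects - 1, features)")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = varfrac[seq_len(n_components)],
       labels = if (inherits(features, "feature_set")) features$labels else NULL)
}

#' Leave-one-out cross-validated confusion counts
#'
#' For each subject, trains the linear SVM on the remaining subjects and
#' classifies the held-out one. The patient group (second factor level) is
#' the positive class for the confusion counts. A fold whose training set
#' lacks one class counts the held-out subject as misclassified.
#'
#' @param features a `feature_set`.
#' @param labels optional label override (same length as subjects), used by
#'   the permutation machinery.
#' @param cost soft-margin cost passed to [svm_train()].
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
loocv_evaluate <- function(features, labels = NULL, cost = 1e4) {
  stopifnot(inherits(features, "feature_set"))
  X <- features$X
  y <- if (is.null(labels)) features$labels else
    factor(labels, levels = levels(features$labels))
  n <- nrow(X)
  if (min(table(y)) < 3)
    warning("fewer than 3 subjects in a class; LOOCV estimates are fragile")
  pos <- levels(y)[2]                     # patient group = positive class
  TP <- FN <- TN <- FP <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    truth <- y[i]
    pred <- if (nlevels(droplevels(ytr)) < 2) {
      # untrainable fold: convention is to count the held-out subject wrong
      setdiff(levels(y), as.character(truth))[1]
    } else {
      m <- svm_train(X[-i, , drop = FALSE], ytr, cost = cost)
      as.character(svm_classify(m, X[i, ]))
    }
    if (truth == pos) {
      if (pred == pos) TP <- TP + 1L else FN <- FN + 1L
    } else {
      if (pred != pos) TN <- TN + 1L else FP <- FP + 1L
    }
  }
  c(TP = TP, FN = FN, TN = TN, FP = FP)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and F-score (harmonic mean of precision and
#' sensitivity), reported as integer percentages truncated toward zero —
#' e.g. 16/19 = 84.2% prints as 84. The F-score is `NA` (flagged) when
#' precision is undefined (`TP + FP = 0`).
#'
#' @param confusion named vector with `TP, FN, TN, FP` (as returned by
#'   [loocv_evaluate()]).
#' @return Named numeric vector `c(accuracy, specificity, sensitivity,
#'   f_score)` in integer percent.
#' @export
classification_metrics <- function(confusion) {
  cts <- confusion[c("TP", "FN", "TN", "FP")]
  if (any(is.na(cts)) || any(cts < 0)) stop("invalid confusion counts")
  TP <- cts[["TP"]]; FN <- cts[["FN"]]; TN <- cts[["TN"]]; FP <- cts[["FP"]]
  if (TP + FN == 0 || TN + FP == 0) stop("both class totals must be positive")
  acc <- (TP + TN) / sum(cts)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  f <- if (TP + FP == 0) NA_real_ else {
    prec <- TP / (TP + FP)
    if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  }
  trunc_pct <- function(x) if (is.na(x)) NA_real_ else trunc(100 * x)
  c(accuracy = trunc_pct(acc), specificity = trunc_pct(spec),
    sensitivity = trunc_pct(sens), f_score = trunc_pct(f))
}

#' Label-permutation significance of classifier performance
#'
#' Runs the full leave-one-out evaluation on the observed labels, then on
#' `n_perm` random label permutations, and reports for each metric the
#' fraction of permuted runs scoring at or above the observed value — the
#' permutation p-value of group separability.
#'
#' @param features a `feature_set`.
#' @param n_perm number of label permutations (default 10000; heavy — each
#'   permutation refits `n` SVMs).
#' @param seed integer seed.
#' @param cost soft-margin cost.
#' @return List of class `classifier_report`: `confusion`, `metrics`
#'   (integer percent), `p_values` (per metric; `NA` when `n_perm = 0`),
#'   `n_perm`, `seed`, `source`.
#' @export
label_permutation_significance <- function(features, n_perm = 10000, seed = 1,
                                           cost = 1e4) {
  stopifnot(inherits(features, "feature_set"))
  conf <- loocv_evaluate(features, cost = cost)
  obs <- classification_metrics(conf)
  if (n_perm > 0) {
    set.seed(seed)
    geq <- numeric(length(obs))
    for (k in seq_len(n_perm)) {
      perm <- sample(features$labels)
      mk <- classification_metrics(
        suppressWarnings(loocv_evaluate(features, labels = perm, cost = cost)))
      geq <- geq + as.numeric(!is.na(mk) & !is.na(obs) & mk >= obs)
    }
    p <- setNames(geq / n_perm, names(obs))
    p[is.na(obs)] <- NA_real_
  } else {
    p <- setNames(rep(NA_real_, length(obs)), names(obs))
  }
  structure(list(confusion = conf, metrics = obs, p_values = p,
                 n_perm = n_perm, seed = seed, source = features$source),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> features: %s; LOOCV confusion TP=%d FN=%d TN=%d FP=%d\n",
              x$source, x$confusion[["TP"]], x$confusion[["FN"]],
              x$confusion[["TN"]], x$confusion[["FP"]]))
  tab <- rbind(percent = x$metrics, p_value = x$p_values)
  print(round(tab, 4))
  invisible(x)
}
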