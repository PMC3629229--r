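test_that("vectorization: order, length, round trip", {
  M <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(vectorize_matrix(M), c(1, 2, 3, 4))
  expect_equal(unvectorize_matrix(vectorize_matrix(M)), M)
  expect_length(vectorize_matrix(matrix(0, 141, 141)), 19881)
  expect_error(vectorize_matrix(matrix(0, 2, 3)), "square")
})

test_that("pca projection: rank, perfect line, two clusters", {
  X <- rbind(c(1, 0, 0), c(0, 1, 0))
  p <- pca_projection(X, n_components = 1)
  expect_equal(p$explained_variance[1], 1)

  # points on a line: first component captures all variance
  t <- seq(-2, 2, length.out = 7)
  Xl <- cbind(t, 2 * t, -t) + 5
  pl <- pca_projection(Xl, n_components = 2)
  expect_equal(pl$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(pl$explained_variance[2], 0, tolerance = 1e-12)
  expect_error(pca_projection(Xl, n_components = 7), "n_components")

  set.seed(1)
  Xc <- rbind(matrix(rnorm(5 * 10, 0, 0.2), 5),
              matrix(rnorm(5 * 10, 3, 0.2), 5))
  pc <- pca_projection(Xc, n_components = 3)
  lab <- rep(1:2, each = 5)
  centers <- apply(pc$coordinates, 2, tapply, lab, mean)
  inter <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  intra <- max(sapply(1:2, function(g)
    mean(sqrt(rowSums(sweep(pc$coordinates[lab == g, ], 2,
                            centers[g, ])^2)))))
  expect_gt(inter, 3 * intra)
})

test_that("linear SVM: hard-margin geometry, stability, affinity", {
  X <- matrix(c(-1, -2, 1, 2), 4, 1)
  y <- factor(c("a", "a", "b", "b"))
  m <- svm_train(X, y)
  # boundary at 0, margin points +-1 are the support vectors
  expect_equal(svm_decision(m, 0), 0, tolerance = 1e-6)
  expect_setequal(m$support, c(1, 3))
  expect_equal(svm_decision(m, -1), 1, tolerance = 1e-4)
  expect_equal(as.character(svm_classify(m, -3)), "a")

  # duplicating an interior (non-support) point leaves the separator unchanged
  set.seed(2)
  X2 <- rbind(matrix(rnorm(10 * 3, -2, 0.3), 10), matrix(rnorm(10 * 3, 2, 0.3), 10))
  y2 <- factor(rep(c("a", "b"), each = 10))
  m1 <- svm_train(X2, y2)
  X3 <- rbind(X2, X2[5, ] * 0.9)          # deep inside class a
  m2 <- svm_train(X3, factor(c(as.character(y2), "a"), levels = c("a", "b")))
  expect_equal(m1$w / sqrt(sum(m1$w^2)), m2$w / sqrt(sum(m2$w^2)),
               tolerance = 1e-3)

  # decision value is affine in the input
  f0 <- svm_decision(m1, rep(0, 3))
  x <- c(1, -2, 0.5)
  expect_equal(svm_decision(m1, 3 * x) - f0,
               3 * (svm_decision(m1, x) - f0), tolerance = 1e-8)

  expect_error(svm_train(X2, factor(rep("a", 20))), "two classes|single-class")
})

test_that("LOOCV: perfect separation, fold count, chance level under null", {
  set.seed(3)
  mats_a <- lapply(1:5, function(k) matrix(rnorm(9, 0, 0.1), 3, 3))
  mats_b <- lapply(1:5, function(k) matrix(rnorm(9, 5, 0.1), 3, 3))
  fs <- feature_set(matrices = c(mats_a, mats_b),
                    groups = factor(rep(c("control", "patient"), each = 5)))
  conf <- loocv_evaluate(fs)
  expect_equal(unname(conf), c(5, 0, 5, 0))   # TP FN TN FP, patient positive

  # 9 + 10 subjects: all 19 folds executed
  mats <- lapply(1:19, function(k) matrix(rnorm(9), 3, 3))
  g <- factor(rep(c("control", "patient"), c(10, 9)))
  fs19 <- feature_set(matrices = mats, groups = g)
  conf19 <- loocv_evaluate(fs19)
  expect_equal(sum(conf19), 19)
  expect_equal(conf19[["TP"]] + conf19[["FN"]], 9)
  expect_equal(conf19[["TN"]] + conf19[["FP"]], 10)

  # labels independent of features: accuracy near chance over repetitions
  set.seed(4)
  accs <- replicate(15, {
    mats <- lapply(1:12, function(k) matrix(rnorm(4), 2, 2))
    fs0 <- feature_set(matrices = mats, groups = factor(rep(c("a", "b"), 6)))
    conf <- loocv_evaluate(fs0)
    (conf[["TP"]] + conf[["TN"]]) / 12
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("classification metrics truncate toward zero like the printed tables", {
  m1 <- classification_metrics(c(TP = 8, FN = 1, TN = 8, FP = 2))
  expect_equal(unname(m1), c(84, 80, 88, 84))
  m2 <- classification_metrics(c(TP = 8, FN = 1, TN = 10, FP = 0))
  expect_equal(unname(m2), c(94, 100, 88, 94))
  m3 <- classification_metrics(c(TP = 4, FN = 0, TN = 6, FP = 0))
  expect_equal(unname(m3), c(100, 100, 100, 100))
  m4 <- classification_metrics(c(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_true(is.na(m4[["f_score"]]))        # precision undefined
  expect_error(classification_metrics(c(TP = 1, FN = -1, TN = 1, FP = 0)),
               "invalid|positive")
})

test_that("label permutation significance: separable cohort, guards, scale invariance", {
  set.seed(5)
  mats <- c(lapply(1:10, function(k) matrix(rnorm(9, 0, 0.3), 3, 3)),
            lapply(1:9, function(k) matrix(rnorm(9, 4, 0.3), 3, 3)))
  g <- factor(rep(c("control", "patient"), c(10, 9)))
  fs <- feature_set(matrices = mats, groups = g)
  rep0 <- label_permutation_significance(fs, n_perm = 0)
  expect_true(all(is.na(rep0$p_values)))
  expect_equal(rep0$metrics[["accuracy"]], 100)

  rep1 <- label_permutation_significance(fs, n_perm = 60, seed = 6)
  expect_lt(rep1$p_values[["accuracy"]], 0.05)

  # scaling all features by a positive constant changes nothing
  fs_scaled <- fs; fs_scaled$X <- 7 * fs$X
  rep2 <- label_permutation_significance(fs_scaled, n_perm = 60, seed = 6)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$p_values, rep2$p_values)
})

test_that("Q features beat W features when only the noise differs between groups", {
  ch <- small_cohort(n_control = 6, n_patient = 6, n_channels = 8,
                     duration = 5, deltas = data.frame(i = integer(), j = integer(),
                                                       delta = numeric()),
                     ell_control = 0.04, ell_patient = 0.2, seed = 21)
  conf_W <- suppressWarnings(loocv_evaluate(feature_set(ch, "W")))
  conf_Q <- suppressWarnings(loocv_evaluate(feature_set(ch, "Q")))
  acc <- function(cf) (cf[["TP"]] + cf[["TN"]]) / sum(cf)
  expect_gt(acc(conf_Q), acc(conf_W))
  expect_gte(acc(conf_Q), 0.9)
})
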