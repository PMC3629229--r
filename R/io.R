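# Canonical text dialect: UTF-8, tab-separated, full-precision scientific
# notation. Recordings: one row per channel, first column "channel" holding
# the channel id, remaining columns the samples. Square matrices (W, Q, C):
# header row of channel ids, one row per channel with the id in the first
# column.

#' Read and write recordings in the canonical text dialect
#'
#' @param path file path.
#' @param dt sampling interval in seconds (recordings do not embed it; it
#'   travels in the cohort manifest).
#' @return `read_recording`: an [mc_recording()].
#' @export
read_recording <- function(path, dt) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "channel") stop("not a recording file: ", path)
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric values in ", path)
  dimnames(X) <- NULL
  mc_recording(X, dt = dt, channel_ids = df$channel)
}

#' @rdname read_recording
#' @param rec an [mc_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  df <- data.frame(channel = rec$channel_ids, rec$data, check.names = FALSE)
  colnames(df) <- c("channel", sprintf("t%d", seq_len(ncol(rec$data))))
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write labelled square matrices (W, Q, ...)
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with channel-id dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  M <- as.matrix(df)
  dimnames(M) <- list(rownames(df), colnames(df))
  M
}

#' @rdname read_matrix_tsv
#' @param M square matrix with channel-id dimnames (or a `conn_matrix`).
#' @export
write_matrix_tsv <- function(M, path) {
  if (inherits(M, "conn_matrix")) M <- M$W
  df <- data.frame(channel = rownames(M),
                   format(M, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("channel", colnames(M))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a sensor layout
#'
#' Delimited text with columns `id, x, y, z` (meters); projected 2-D
#' coordinates `px, py` are recomputed by stereographic projection when not
#' present in the file.
#'
#' @param path file path.
#' @return A `sensor_layout` data.frame.
#' @export
read_layout <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df))) stop("layout must have columns id, x, y, z")
  if (anyDuplicated(df$id)) stop("duplicate sensor ids in layout")
  if (!all(c("px", "py") %in% names(df))) {
    p2 <- stereographic_projection(as.matrix(df[, c("x", "y", "z")]))
    df$px <- p2[, 1]; df$py <- p2[, 2]
  }
  class(df) <- c("sensor_layout", "data.frame")
  df
}

#' @rdname read_layout
#' @param layout a `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  write.table(format(as.data.frame(layout), digits = 17, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk with a manifest
#'
#' Writes one recording file per subject, the layout, a ground-truth JSON
#' and a JSON manifest tying them together ([load_cohort()] reads it back).
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay_path <- file.path(dir, "layout.tsv")
  write_layout(cohort$layout, lay_path)
  subjects <- lapply(cohort$subjects, function(s) {
    p <- file.path(dir, paste0(s$id, ".tsv"))
    write_recording(s$recording, p)
    list(id = s$id, path = basename(p), group = s$group,
         artifact_components = 0L)
  })
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$base_W <- NULL   # matrices go to their own files
    write_matrix_tsv(cohort$ground_truth$base_W, file.path(dir, "base_W.tsv"))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(dt = cohort$dt, layout = "layout.tsv",
                   channels = cohort$layout$id, subjects = subjects)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' Reads the JSON manifest, loads every referenced recording, restricts each
#' to the retained channel list (in manifest order), centers the signals and
#' removes the per-subject number of artifact principal components recorded
#' in the manifest. Errors name the offending subject and channel.
#'
#' @param manifest_path path to `manifest.json`.
#' @return A `cohort` (without fits; see [fit_cohort()]).
#' @export
load_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  if (is.null(man$dt) || man$dt <= 0) stop("manifest lacks a valid dt")
  layout <- read_layout(file.path(base, man$layout))
  channels <- as.character(man$channels)
  subs_df <- as.data.frame(man$subjects)
  if (length(unique(subs_df$group)) != 2)
    stop("manifest must define exactly two group labels")
  subjects <- lapply(seq_len(nrow(subs_df)), function(k) {
    row <- subs_df[k, ]
    p <- file.path(base, row$path)
    if (!file.exists(p)) stop("missing recording file for subject ", row$id)
    rec <- read_recording(p, dt = man$dt)
    missing <- setdiff(channels, rec$channel_ids)
    if (length(missing) > 0)
      stop("subject ", row$id, " lacks retained channel(s): ",
           paste(missing, collapse = ", "))
    rec$data <- rec$data[channels, , drop = FALSE]
    rec$channel_ids <- channels
    rec <- center_signals(rec)
    ac <- row$artifact_components
    if (!is.null(ac) && !is.na(ac) && ac > 0)
      rec <- remove_artifact_components(rec, ac)
    list(id = row$id, group = row$group, recording = rec)
  })
  lay_ids <- layout$id
  if (!all(channels %in% lay_ids))
    stop("layout lacks some retained channels")
  layout <- layout[match(channels, lay_ids), , drop = FALSE]
  structure(list(subjects = subjects,
                 groups = factor(vapply(subjects, `[[`, "", "group")),
                 layout = layout, dt = man$dt, ground_truth = NULL),
            class = "cohort")
}

#' Run the full group-comparison pipeline
#'
#' End-to-end driver reproducing the analysis sequence on a loaded or
#' simulated cohort: per-subject model fits (drift, noise covariances,
#' stability, residual diagnostics), connection-wise change maps with
#' permutation z-scores, ranked dominant changes, excitation/inhibition
#' balance comparison, W-based and Q-based classifier reports with
#' label-permutation significance, dominant-noise-pattern spatial
#' complexities with a rank-sum group comparison, and per-subject cross-talk
#' profiles. Fully deterministic given `seed`.
#'
#' @param cohort a `cohort` (or a manifest path).
#' @param n_perm permutations for connection-wise tests (default 1000).
#' @param n_perm_labels label permutations for the classifiers (default 500).
#' @param lag_steps fitting lag (samples).
#' @param seed master seed.
#' @param top_k how many ranked changes to retain (default 10).
#' @return List of class `comparison_bundle`.
#' @export
run_full_comparison <- function(cohort, n_perm = 1000, n_perm_labels = 500,
                                lag_steps = 1L, seed = 1, top_k = 10) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))
  tab <- table(cohort$groups)
  if (length(tab) < 2 || any(tab == 0))
    stop("empty group: both groups need at least one subject")
  groups <- cohort_groups(cohort)
  cohort <- fit_cohort(cohort, lag_steps = lag_steps)

  per_subject <- lapply(cohort$subjects, function(s) {
    f <- s$fit
    diag <- residual_diagnostics(f$noise)
    list(id = s$id, group = s$group,
         max_real_part = f$stability$max_real_part,
         stable = f$stability$stable,
         q_agreement = f$noise$agreement,
         whiteness = diag$whiteness_score,
         max_abs_skewness = max(abs(diag$skewness)),
         balance = balance_analysis(f$W)$correlations,
         crosstalk_r = crosstalk_profile(f$C0, cohort$layout)$r)
  })

  maps <- connectionwise_changes(cohort, n_perm = n_perm,
                                 seed = derive_seed(seed, 2))
  ranked <- rank_changes(maps, k = top_k)

  report_W <- label_permutation_significance(
    feature_set(cohort, "W"), n_perm = n_perm_labels,
    seed = derive_seed(seed, 3))
  report_Q <- label_permutation_significance(
    feature_set(cohort, "Q"), n_perm = n_perm_labels,
    seed = derive_seed(seed, 4))

  complexity <- vapply(cohort$subjects, function(s)
    spatial_complexity(dominant_noise_pattern(s$fit$noise$Q_empirical),
                       cohort$layout), numeric(1))
  ctrl <- levels(groups)[1]
  cx_test <- ranksum_compare(complexity[groups == ctrl],
                             complexity[groups != ctrl])
  stab_test <- ranksum_compare(
    vapply(per_subject[groups == ctrl], `[[`, 0, "max_real_part"),
    vapply(per_subject[groups != ctrl], `[[`, 0, "max_real_part"))
  xt_test <- ranksum_compare(
    vapply(per_subject[groups == ctrl], `[[`, 0, "crosstalk_r"),
    vapply(per_subject[groups != ctrl], `[[`, 0, "crosstalk_r"))

  structure(list(
    config = list(n_perm = n_perm, n_perm_labels = n_perm_labels,
                  lag_steps = lag_steps, seed = seed,
                  n_channels = nrow(cohort$layout),
                  groups = as.list(table(groups))),
    per_subject = per_subject,
    change_maps = maps,
    ranked_changes = ranked,
    classifier_W = report_W,
    classifier_Q = report_Q,
    complexity = list(values = setNames(complexity,
                                        vapply(cohort$subjects, `[[`, "", "id")),
                      groups = as.character(groups),
                      median_control = median(complexity[groups == ctrl]),
                      median_patient = median(complexity[groups != ctrl]),
                      ranksum_p = cx_test$p_value),
    stability_ranksum_p = stab_test$p_value,
    crosstalk_ranksum_p = xt_test$p_value),
    class = "comparison_bundle")
}

#' @export
print.comparison_bundle <- function(x, ...) {
  cat("<comparison_bundle>\n")
  cat(sprintf("  channels: %d, subjects: %s\n", x$config$n_channels,
              paste(unlist(x$config$groups), names(x$config$groups),
                    collapse = " + ")))
  top <- x$ranked_changes$absolute[1, ]
  cat(sprintf("  top |z|-weighted change: %s -> %s (%.3g)\n",
              top$source, top$target, top$value))
  cat(sprintf("  W classifier accuracy: %g%% (p = %.4g)\n",
              x$classifier_W$metrics[["accuracy"]],
              x$classifier_W$p_values[["accuracy"]]))
  cat(sprintf("  Q classifier accuracy: %g%% (p = %.4g)\n",
              x$classifier_Q$metrics[["accuracy"]],
              x$classifier_Q$p_values[["accuracy"]]))
  cat(sprintf("  complexity medians: control %.4g vs patient %.4g (ranksum p = %.4g)\n",
              x$complexity$median_control, x$complexity$median_patient,
              x$complexity$ranksum_p))
  invisible(x)
}

#' Serialize a comparison bundle to JSON
#'
#' Writes the bundle (matrices flattened with dimension metadata) as a
#' deterministic JSON report: identical inputs and seeds yield byte-identical
#' files.
#'
#' @param bundle a `comparison_bundle`.
#' @param path output file.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "comparison_bundle"))
  simplify <- function(x) {
    if (inherits(x, c("perm_test", "classifier_report", "change_maps",
                      "comparison_bundle")))
      x <- unclass(x)
    if (is.matrix(x))
      return(list(.matrix = TRUE, dim = dim(x), ids = rownames(x),
                  values = as.vector(x)))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  jsonlite::write_json(simplify(bundle), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
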