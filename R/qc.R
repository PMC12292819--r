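# Stratified fold assignment: each class is spread evenly across folds.
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

as_count_matrix <- function(x) {
  if (inherits(x, "otu_table")) x$counts else as.matrix(x)
}

#' Chi-squared univariate feature screening
#'
#' Ranks features by the chi-squared statistic between per-class feature
#' totals and the class prior (the nonnegative-count analogue of a
#' contingency test), and keeps the `k` largest. Ties are broken by
#' ascending feature index; when `k >= ncol(X)` every feature is kept.
#'
#' @param X nonnegative matrix (samples x features).
#' @param labels class labels (exactly 2 classes).
#' @param k number of features to keep.
#' @return sorted integer vector of selected feature indices, with the
#'   per-feature statistics as attribute `"statistic"`.
#' @export
screen_features_chi2 <- function(X, labels, k) {
  X <- as_count_matrix(X)
  if (any(X < 0)) stop("screen_features_chi2: negative entries")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("screen_features_chi2: single class")
  if (k < 1) stop("k must be >= 1")
  prior <- as.numeric(table(labels)) / length(labels)
  obs <- rowsum(X, labels)                       # classes x features
  tot <- colSums(obs)
  expd <- outer(prior, tot)
  stat <- colSums((obs - expd)^2 / expd)
  stat[!is.finite(stat)] <- 0                    # all-zero features carry no signal
  k <- min(k, ncol(X))
  sel <- sort(order(-stat, seq_along(stat))[seq_len(k)])
  attr(sel, "statistic") <- stat
  sel
}

binary_metrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  acc <- mean(pred == truth)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Random-search tuning of the polynomial-kernel SVC
#'
#' Seeded random search with log-uniform draws of the regularization
#' strength `C` over `[0.01, 1000]` and kernel coefficient `gamma` over
#' `[0.0001, 100]`; the objective is mean stratified cross-validated
#' accuracy and the best of `n_trials` trials is returned.
#'
#' @param X feature matrix.
#' @param labels binary labels (>= 2 samples per class).
#' @param n_trials number of random trials (default 100).
#' @param folds cross-validation folds for the objective.
#' @param seed RNG seed.
#' @return list with `C`, `gamma`, `kernel = "polynomial"`, the winning
#'   `cv_accuracy` and the full `trials` data.frame.
#' @export
tune_polynomial_svc <- function(X, labels, n_trials = 100, folds = 5, seed = 1) {
  X <- as_count_matrix(X)
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("tune_polynomial_svc: need >= 2 samples per class")
  draws <- with_seed(seed, data.frame(
    C = 10^stats::runif(n_trials, log10(0.01), log10(1000)),
    gamma = 10^stats::runif(n_trials, log10(1e-4), log10(100))))
  fold <- stratified_folds(labels, folds, seed)
  acc <- vapply(seq_len(n_trials), function(t) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- suppressWarnings(e1071::svm(
        x = X[tr, , drop = FALSE], y = labels[tr], kernel = "polynomial",
        cost = draws$C[t], gamma = draws$gamma[t], scale = FALSE))
      mean(predict(fit, X[!tr, , drop = FALSE]) == labels[!tr])
    }, 0))
  }, 0)
  best <- which.max(acc)
  list(C = draws$C[best], gamma = draws$gamma[best], kernel = "polynomial",
       cv_accuracy = acc[best],
       trials = cbind(draws, cv_accuracy = acc))
}

#' Adversarial real-versus-synthetic quality report
#'
#' Merges real and synthetic samples (balancing class sizes by seeded
#' subsampling of the larger side), labels real = 0 / synthetic = 1,
#' screens to `k` features by chi-squared, and cross-validates a logistic
#' regression and a polynomial-kernel SVC on the merged set. Synthesis
#' passes the gate when the best mean accuracy does not exceed the
#' discriminability ceiling: a synthesizer is good precisely when
#' classifiers cannot tell its output from real data.
#'
#' @param real,synthetic `otu_table`s or matrices over the same features.
#' @param svc_params optional list with `C` and `gamma` (e.g. from
#'   [tune_polynomial_svc()]); defaults to `C = 1`, `gamma = 1/k`.
#' @param k number of screened features (default 500, capped at the
#'   feature count).
#' @param folds cross-validation folds.
#' @param ceiling accuracy ceiling for the pass verdict (default 0.75).
#' @param seed RNG seed.
#' @return a `qc_report`: per-classifier metrics, `screened_feature_count`,
#'   `best_accuracy` and `verdict` (`"pass"`/`"fail"`).
#' @export
adversarial_report <- function(real, synthetic, svc_params = NULL, k = 500,
                               folds = 5, ceiling = 0.75, seed = 1) {
  Xr <- as_count_matrix(real); Xs <- as_count_matrix(synthetic)
  if (nrow(Xr) == 0 || nrow(Xs) == 0) stop("adversarial_report: empty input")
  if (ncol(Xr) != ncol(Xs)) stop("adversarial_report: feature axes differ")
  with_seed(seed, {
    n <- min(nrow(Xr), nrow(Xs))
    if (nrow(Xr) > n) Xr <- Xr[sample.int(nrow(Xr), n), , drop = FALSE]
    if (nrow(Xs) > n) Xs <- Xs[sample.int(nrow(Xs), n), , drop = FALSE]
  })
  X <- rbind(Xr, Xs)
  y <- factor(rep(c("real", "synthetic"), c(nrow(Xr), nrow(Xs))))
  sel <- screen_features_chi2(X, y, k)
  X <- X[, sel, drop = FALSE]
  fold <- stratified_folds(y, folds, seed)
  if (is.null(svc_params)) svc_params <- list(C = 1, gamma = 1 / length(sel))
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    dtr <- data.frame(y = as.integer(y[tr] == "synthetic"), X[tr, , drop = FALSE])
    dte <- data.frame(X[!tr, , drop = FALSE])
    lr <- suppressWarnings(stats::glm(y ~ ., data = dtr, family = stats::binomial()))
    p_lr <- suppressWarnings(stats::predict(lr, newdata = dte, type = "response"))
    pred_lr <- factor(ifelse(p_lr > 0.5, "synthetic", "real"), levels = levels(y))
    sv <- suppressWarnings(e1071::svm(
      x = X[tr, , drop = FALSE], y = y[tr], kernel = "polynomial",
      cost = svc_params$C, gamma = svc_params$gamma, scale = FALSE,
      probability = TRUE))
    pred_sv <- predict(sv, X[!tr, , drop = FALSE])
    rbind(logistic_regression = binary_metrics(y[!tr], pred_lr, "synthetic"),
          polynomial_svc = binary_metrics(y[!tr], pred_sv, "synthetic"))
  })
  metrics <- Reduce(`+`, per_fold) / folds
  metrics <- data.frame(classifier = rownames(metrics), metrics,
                        row.names = NULL, stringsAsFactors = FALSE)
  best <- max(metrics$accuracy)
  structure(list(metrics = metrics, screened_feature_count = length(sel),
                 best_accuracy = best, ceiling = ceiling,
                 verdict = if (best <= ceiling) "pass" else "fail"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Adversarial real-vs-synthetic QC (", x$screened_feature_count,
      " screened features)\n", sep = "")
  print(x$metrics, digits = 3)
  cat("best accuracy:", round(x$best_accuracy, 3), "ceiling:", x$ceiling,
      "->", x$verdict, "\n")
  invisible(x)
}

#' Per-feature Kolmogorov-Smirnov battery with Bonferroni correction
#'
#' Two-sample KS test per feature column between real and synthetic
#' samples. Sample counts are equalized by seeded subsampling of the
#' larger table. P-values are Bonferroni-adjusted over the number of
#' features tested; a feature constant and identical in both tables is
#' reported with statistic 0 and p-value 1.
#'
#' @param real_table,synth_table `otu_table`s or matrices with identical
#'   feature axes.
#' @param alpha family-wise significance level (default 0.05).
#' @param seed RNG seed for the pairing subsample.
#' @return data.frame with `feature_id`, `statistic`, `p_raw`,
#'   `p_adjusted` and `reject`.
#' @export
ks_battery <- function(real_table, synth_table, alpha = 0.05, seed = 1) {
  Xr <- as_count_matrix(real_table); Xs <- as_count_matrix(synth_table)
  if (ncol(Xr) != ncol(Xs) ||
      (!is.null(colnames(Xr)) && !is.null(colnames(Xs)) &&
       !identical(colnames(Xr), colnames(Xs))))
    stop("ks_battery: mismatched feature axes")
  with_seed(seed, {
    n <- min(nrow(Xr), nrow(Xs))
    if (nrow(Xr) > n) Xr <- Xr[sort(sample.int(nrow(Xr), n)), , drop = FALSE]
    if (nrow(Xs) > n) Xs <- Xs[sort(sample.int(nrow(Xs), n)), , drop = FALSE]
  })
  p <- ncol(Xr)
  ids <- colnames(Xr)
  if (is.null(ids)) ids <- paste0("F", seq_len(p))
  res <- vapply(seq_len(p), function(j) {
    x <- Xr[, j]; y <- Xs[, j]
    if (length(unique(c(x, y))) == 1) return(c(0, 1))
    kt <- suppressWarnings(stats::ks.test(x, y))
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2))
  p_raw <- res[2, ]
  p_adj <- pmin(1, p_raw * p)
  data.frame(feature_id = ids, statistic = res[1, ], p_raw = p_raw,
             p_adjusted = p_adj, reject = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Column-wise similarity statistics between paired tables
#'
#' For each feature column of two row-aligned tables of equal shape:
#' absolute mean difference, absolute standard-deviation difference,
#' Spearman correlation of the paired vectors, and mean squared row-wise
#' difference; aggregated as means over columns (Spearman over
#' nonconstant column pairs).
#'
#' @param real_table,synth_table equal-shape tables/matrices, rows paired.
#' @return list with `per_column` data.frame and `aggregate` named vector
#'   (`mean_difference`, `std_difference`, `spearman_correlation`, `mse`).
#' @export
column_similarity <- function(real_table, synth_table) {
  Xr <- as_count_matrix(real_table); Xs <- as_count_matrix(synth_table)
  if (!all(dim(Xr) == dim(Xs))) stop("column_similarity: shape mismatch")
  p <- ncol(Xr)
  ids <- colnames(Xr); if (is.null(ids)) ids <- paste0("F", seq_len(p))
  per <- data.frame(
    feature_id = ids,
    mean_difference = abs(colMeans(Xr) - colMeans(Xs)),
    std_difference = abs(apply(Xr, 2, stats::sd) - apply(Xs, 2, stats::sd)),
    spearman = vapply(seq_len(p), function(j) {
      if (stats::sd(Xr[, j]) == 0 || stats::sd(Xs[, j]) == 0) return(NA_real_)
      suppressWarnings(stats::cor(Xr[, j], Xs[, j], method = "spearman"))
    }, 0),
    mse = colMeans((Xr - Xs)^2),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_column = per,
       aggregate = c(mean_difference = mean(per$mean_difference),
                     std_difference = mean(per$std_difference),
                     spearman_correlation = mean(per$spearman, na.rm = TRUE),
                     mse = mean(per$mse)))
}

#' Retain the synthetic samples hardest to tell from real
#'
#' Given one adversarial-classifier score (probability of being
#' synthetic) per synthetic sample, retains samples misclassified as real
#' (score < 0.5) or with score margin `|p - 0.5|` below the configured
#' threshold. Deterministic given the scores.
#'
#' @param synthetic an `otu_table` (or matrix) of synthetic samples.
#' @param classifier_scores numeric vector, one score per sample.
#' @param rule list with `margin` (default 0.1) and
#'   `include_misclassified` (default `TRUE`).
#' @return list with `table` (retained subset) and `retained` (logical
#'   vector).
#' @export
retain_hard_synthetic <- function(synthetic, classifier_scores,
                                  rule = list(margin = 0.1, include_misclassified = TRUE)) {
  X <- as_count_matrix(synthetic)
  if (length(classifier_scores) != nrow(X))
    stop("retain_hard_synthetic: ", length(classifier_scores),
         " scores for ", nrow(X), " samples")
  margin <- if (is.null(rule$margin)) 0.1 else rule$margin
  mis <- if (isTRUE(rule$include_misclassified)) classifier_scores < 0.5 else FALSE
  keep <- mis | abs(classifier_scores - 0.5) < margin
  sub <- X[keep, , drop = FALSE]
  out <- if (inherits(synthetic, "otu_table")) otu_table(sub) else sub
  list(table = out, retained = keep)
}
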