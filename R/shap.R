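all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- vector("list", p * length(sub))
  k <- 0
  for (i in seq_len(p)) {
    rest <- setdiff(seq_len(p), i)
    for (s in sub) {
      k <- k + 1
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' Shapley attributions for a fitted classifier
#'
#' Two routes are provided. `"tree_exact"` uses the path-dependent exact
#' tree decomposition available for gradient-boosted tree ensembles
#' (attributions in margin/log-odds space; additivity to the margin is
#' exact up to floating point). `"permutation_sampled"` is a
#' model-agnostic sampled-permutation estimator against a background
#' reference: for each permutation, features are switched from the
#' background value to the sample's value in order and the output
#' differences are accredited to the switched feature. With a single
#' background row each permutation telescopes, so additivity
#' `base_value + sum(values) = f(x)` is exact for the estimator's value
#' function.
#'
#' @param model an `xgb.Booster` (for `"tree_exact"`), or any object for
#'   `"permutation_sampled"` provided `predict_fun` is given.
#' @param X samples to attribute (matrix or `otu_table`).
#' @param background background reference row(s) for the sampled method;
#'   conventionally the training-subset feature means.
#' @param method `"tree_exact"` or `"permutation_sampled"`.
#' @param predict_fun for the sampled method: function mapping a feature
#'   matrix to numeric model outputs. Defaults to [predict_crc_score()]
#'   output for the supported classifiers.
#' @param n_perm permutations per sample for the sampled method.
#' @param seed RNG seed for the sampled method.
#' @param meta optional sample metadata; when given, per-specimen
#'   sub-reports (stool/biopsy/saliva rankings) are attached.
#' @return an `attribution_report`: `base_value`, `values` (samples x
#'   features), `predictions` (model output per sample),
#'   `additivity_residuals`, `ranking` (features by mean absolute value)
#'   and optionally `by_specimen`.
#' @export
shap_attributions <- function(model, X, background = NULL,
                              method = c("tree_exact", "permutation_sampled"),
                              predict_fun = NULL, n_perm = 64, seed = 1,
                              meta = NULL) {
  method <- match.arg(method)
  Xm <- as_count_matrix(X)
  ids <- colnames(Xm); if (is.null(ids)) ids <- paste0("F", seq_len(ncol(Xm)))
  if (method == "tree_exact") {
    if (!inherits(model, "xgb.Booster"))
      stop("tree_exact requires a gradient-boosted tree model (xgb.Booster)")
    contrib <- predict(model, Xm, predcontrib = TRUE)
    p <- ncol(Xm)
    values <- contrib[, seq_len(p), drop = FALSE]
    base <- contrib[, p + 1]
    preds <- predict(model, Xm, outputmargin = TRUE)
    base_value <- base[1]
    resid <- base + rowSums(values) - preds
  } else {
    if (is.null(predict_fun)) predict_fun <- function(M) predict_crc_score(model, M)
    if (is.null(background)) stop("permutation_sampled needs a background")
    bg <- as_count_matrix(background)
    if (nrow(bg) > 1) bg <- matrix(colMeans(bg), 1, dimnames = list(NULL, colnames(bg)))
    p <- ncol(Xm)
    base_value <- as.numeric(predict_fun(bg))
    values <- matrix(0, nrow(Xm), p)
    # all p! orders when affordable (the estimator is then exact);
    # otherwise a seeded sample of permutations
    if (p <= 8 && factorial(p) <= n_perm) {
      perms <- all_permutations(p)
      n_perm <- length(perms)
    } else {
      perms <- with_seed(seed, lapply(seq_len(n_perm), function(i) sample.int(p)))
    }
    for (s in seq_len(nrow(Xm))) {
      x <- Xm[s, ]
      phi <- numeric(p)
      for (perm in perms) {
        # rows 1..p+1: background with the first i-1 permuted features set to x
        M <- matrix(bg, p + 1, p, byrow = TRUE)
        for (i in seq_len(p)) M[(i + 1):(p + 1), perm[i]] <- x[perm[i]]
        out <- predict_fun(M)
        phi[perm] <- phi[perm] + diff(out)
      }
      values[s, ] <- phi / n_perm
    }
    preds <- as.numeric(predict_fun(Xm))
    resid <- base_value + rowSums(values) - preds
  }
  colnames(values) <- ids
  rownames(values) <- rownames(Xm)
  mean_abs <- colMeans(abs(values))
  ord <- order(-mean_abs, seq_along(mean_abs))
  ranking <- data.frame(feature_id = ids[ord], mean_abs_value = mean_abs[ord],
                        rank = seq_along(ord), row.names = NULL,
                        stringsAsFactors = FALSE)
  rep <- structure(list(method = method, base_value = base_value,
                        values = values, predictions = preds,
                        additivity_residuals = resid, ranking = ranking),
                   class = "attribution_report")
  if (!is.null(meta)) {
    meta <- meta[match(rownames(Xm), meta$sample_id), , drop = FALSE]
    rep$by_specimen <- lapply(split(seq_len(nrow(Xm)), meta$specimen), function(idx) {
      v <- values[idx, , drop = FALSE]
      ma <- colMeans(abs(v))
      o <- order(-ma, seq_along(ma))
      list(sample_ids = rownames(Xm)[idx],
           ranking = data.frame(feature_id = ids[o], mean_abs_value = ma[o],
                                rank = seq_along(o), row.names = NULL,
                                stringsAsFactors = FALSE))
    })
  }
  rep
}

#' Export attribution plot data
#'
#' Produces the three tabular views behind the standard attribution
#' figures: (a) `summary` — features ranked by mean absolute attribution;
#' (b) `beeswarm` — per-sample (feature value, attribution) pairs;
#' (c) `force` — per-sample contribution sequences, samples laid out all
#' AP first then all CRC, features ordered by descending absolute
#' attribution within each sample. When `dir` is given the three tables
#' are written as TSVs.
#'
#' @param report an `attribution_report`.
#' @param X the attributed feature matrix (for feature values).
#' @param meta optional metadata (drives the AP-then-CRC force layout).
#' @param dir optional output directory.
#' @return list of data.frames `summary`, `beeswarm`, `force`.
#' @export
export_plot_data <- function(report, X, meta = NULL, dir = NULL) {
  stopifnot(inherits(report, "attribution_report"))
  Xm <- as_count_matrix(X)
  v <- report$values
  sample_ids <- rownames(v); if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(v)))
  feature_ids <- colnames(v)
  sample_order <- seq_len(nrow(v))
  if (!is.null(meta)) {
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
    sample_order <- order(condition_factor(meta$condition))
  }
  beeswarm <- data.frame(
    sample_id = rep(sample_ids, times = ncol(v)),
    feature_id = rep(feature_ids, each = nrow(v)),
    feature_value = as.vector(Xm),
    shap_value = as.vector(v),
    stringsAsFactors = FALSE)
  force <- do.call(rbind, lapply(seq_along(sample_order), function(pos) {
    s <- sample_order[pos]
    o <- order(-abs(v[s, ]), seq_len(ncol(v)))
    data.frame(sample_position = pos, sample_id = sample_ids[s],
               condition = if (is.null(meta)) NA_character_ else meta$condition[s],
               feature_id = feature_ids[o], shap_value = v[s, o],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out <- list(summary = report$ranking, beeswarm = beeswarm, force = force)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      data.table::fwrite(out[[nm]], file.path(dir, paste0("shap_", nm, ".tsv")),
                         sep = "\t")
  }
  out
}
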