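#' LRP configuration
#'
#' @param epsilon stabilizer added to the denominators (`>= 0`). The
#'   default `NULL` uses a relative stabilizer per layer,
#'   `0.01 * mean(|z|)`, which is scale-free.
#' @param output_seed where backward relevance starts: the pre-sigmoid
#'   `"logit"` (default) or the sigmoid `"probability"`.
#' @param aggregation how per-sample relevances are pooled across samples
#'   and folds: `"mean_abs"` (default) or `"mean_signed"`.
#' @return an `lrp_config`.
#' @export
lrp_config <- function(epsilon = NULL, output_seed = c("logit", "probability"),
                       aggregation = c("mean_abs", "mean_signed")) {
  if (!is.null(epsilon) && epsilon < 0) stop("epsilon must be >= 0")
  structure(list(epsilon = epsilon, output_seed = match.arg(output_seed),
                 aggregation = match.arg(aggregation)),
            class = "lrp_config")
}

#' Layer-wise relevance propagation with the epsilon rule
#'
#' Runs a forward pass caching activations, seeds the output relevance at
#' the pre-sigmoid logit (or the sigmoid probability), and iterates
#' backwards through the dense layers applying
#' \deqn{R_j = \sum_k \frac{a_j w_{jk}}{z_k + \epsilon\,\mathrm{sign}(z_k)} R_k,
#'       \qquad z_k = \sum_j a_j w_{jk} + b_k,}
#' with `sign(0) := 1`. Bias relevance is absorbed, so the relevance sum
#' is conserved exactly only for zero-bias networks as `epsilon -> 0`.
#'
#' @param net a trained `dense_net`.
#' @param x a single input vector (same feature space the net was
#'   trained in, i.e. standardized if training inputs were).
#' @param config an [lrp_config()].
#' @return named numeric vector of per-input relevances.
#' @export
lrp_epsilon <- function(net, x, config = lrp_config()) {
  stopifnot(inherits(net, "dense_net"))
  x <- as.numeric(x)
  if (length(x) != nrow(net$weights[[1]]))
    stop("lrp_epsilon: input length ", length(x), " != ",
         nrow(net$weights[[1]]), " features")
  fw <- forward_dense(net, matrix(x, 1))
  L <- length(net$weights)
  R <- if (config$output_seed == "logit") fw$logit else fw$prob
  R <- as.numeric(R)
  for (l in rev(seq_len(L))) {
    a <- as.numeric(fw$activations[[l]])
    z <- as.numeric(fw$preactivations[[l]])
    eps <- if (is.null(config$epsilon)) 0.01 * mean(abs(z)) else config$epsilon
    if (eps == 0 && any(z == 0))
      stop("lrp_epsilon: zero pre-activation with epsilon = 0; increase epsilon")
    denom <- z + eps * ifelse(z >= 0, 1, -1)
    R <- a * as.numeric(net$weights[[l]] %*% (R / denom))
  }
  names(R) <- rownames(net$weights[[1]])
  R
}

# Per-feature z-scoring with training statistics; zero-variance features
# are left centered only.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}
standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
}

#' Select the balanced extraction subset
#'
#' Per condition, draws a seeded random subset of size equal to the
#' largest multiple of 3 not exceeding `fraction` times the per-condition
#' total, taken equally from the three specimens. With the study layout
#' (190 samples per condition, fraction 0.10) this is 18 samples per
#' condition (6 per specimen), leaving 172 per condition for the
#' downstream classifiers.
#'
#' @param table an `otu_table`.
#' @param meta matching metadata (all three specimens present).
#' @param fraction target subset fraction per condition (default 0.10).
#' @param seed RNG seed.
#' @return list with `subset` and `remainder`, each a list of `table`
#'   and `meta`; the two partitions are disjoint and exhaustive.
#' @export
select_extraction_subset <- function(table, meta, fraction = 0.10, seed = 1) {
  validate_otu_table(table)
  validate_sample_meta(meta, table)
  meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
  take <- character(0)
  with_seed(seed, {
    for (cond in unique(meta$condition)) {
      n_cond <- sum(meta$condition == cond)
      quota <- floor(fraction * n_cond / 3)   # per specimen
      if (quota == 0) next
      for (spec in .SPECIMENS) {
        ids <- meta$sample_id[meta$condition == cond & meta$specimen == spec]
        if (length(ids) < quota)
          stop("specimen group ", cond, "/", spec, " has ", length(ids),
               " samples; quota is ", quota)
        take <- c(take, sample(ids, quota))
      }
    }
  })
  keep <- meta$sample_id %in% take
  sub_meta <- meta[keep, , drop = FALSE]; rownames(sub_meta) <- NULL
  rem_meta <- meta[!keep, , drop = FALSE]; rownames(rem_meta) <- NULL
  list(subset = list(table = subset_otu(table, samples = which(keep)),
                     meta = sub_meta),
       remainder = list(table = subset_otu(table, samples = which(!keep)),
                        meta = rem_meta))
}

#' Compare hidden activations under paired cross-validation
#'
#' Trains the dense network under stratified k-fold cross-validation once
#' per activation variant, with identical fold assignment and per-fold
#' seeds across variants so the comparison is paired. Inputs are
#' z-scored with training-fold statistics.
#'
#' @param X feature matrix or `otu_table`.
#' @param labels binary labels.
#' @param activations character vector of activation names to sweep.
#' @param spec base [dense_net_spec()] (its activation field is
#'   overridden per variant).
#' @param folds cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment and per-fold net seeds.
#' @return list with `results` (data.frame of activation, mean_accuracy)
#'   and `best` (argmax, ties going to the first listed).
#' @export
activation_sweep <- function(X, labels, activations = .ACTIVATIONS,
                             spec = dense_net_spec(), folds = 10, seed = 1) {
  X <- as_count_matrix(X)
  y <- as_binary_labels(labels)
  if (min(table(y)) < folds)
    stop("activation_sweep: fewer samples per class than folds")
  fold <- stratified_folds(y, folds, seed)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max, folds))
  acc <- vapply(activations, function(act) {
    vspec <- spec; vspec$activation <- act
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      st <- standardize_fit(X[tr, , drop = FALSE])
      vspec$seed <- fold_seeds[f]
      net <- train_dense_net(standardize_apply(X[tr, , drop = FALSE], st),
                             y[tr], vspec)
      pred <- predict(net, standardize_apply(X[!tr, , drop = FALSE], st),
                      type = "class")
      mean(pred == y[!tr])
    }, 0))
  }, 0)
  results <- data.frame(activation = activations, mean_accuracy = unname(acc),
                        stringsAsFactors = FALSE)
  list(results = results, best = activations[which.max(acc)])
}

#' Cross-validated LRP feature extraction
#'
#' Under stratified k-fold cross-validation: train the dense network on
#' the fold's training part (inputs z-scored with training-fold
#' statistics), compute LRP-epsilon relevances for every validation
#' sample, and aggregate per-feature scores (mean absolute relevance by
#' default) across samples and folds. Features are ranked by the pooled
#' score; ties break by ascending feature index.
#'
#' @param X feature matrix or `otu_table`.
#' @param labels binary labels.
#' @param spec a [dense_net_spec()].
#' @param config an [lrp_config()].
#' @param folds cross-validation folds (default 10).
#' @param k number of top features to return (default 64).
#' @param seed RNG seed.
#' @return list with `relevance` (data.frame: feature_id, score, rank),
#'   `top_features` (the k highest-scoring feature ids),
#'   `fold_accuracy` and `mean_accuracy`.
#' @export
cross_validated_extraction <- function(X, labels, spec = dense_net_spec(),
                                       config = lrp_config(), folds = 10,
                                       k = 64, seed = 1) {
  X <- as_count_matrix(X)
  y <- as_binary_labels(labels)
  if (k > ncol(X)) stop("k (", k, ") exceeds feature count (", ncol(X), ")")
  fold <- stratified_folds(y, folds, seed)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max, folds))
  score_folds <- matrix(0, folds, ncol(X))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    st <- standardize_fit(X[tr, , drop = FALSE])
    fspec <- spec; fspec$seed <- fold_seeds[f]
    net <- train_dense_net(standardize_apply(X[tr, , drop = FALSE], st),
                           y[tr], fspec)
    Xv <- standardize_apply(X[!tr, , drop = FALSE], st)
    rel <- t(apply(Xv, 1, function(x) lrp_epsilon(net, x, config)))
    if (config$aggregation == "mean_abs") rel <- abs(rel)
    score_folds[f, ] <- colMeans(rel)
    fold_acc[f] <- mean(predict(net, Xv, type = "class") == y[!tr])
  }
  score <- colMeans(score_folds)
  ids <- colnames(X); if (is.null(ids)) ids <- paste0("F", seq_len(ncol(X)))
  ord <- order(-score, seq_along(score))
  relevance <- data.frame(feature_id = ids[ord], score = score[ord],
                          rank = seq_along(ord), stringsAsFactors = FALSE)
  list(relevance = relevance, top_features = ids[ord[seq_len(k)]],
       fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc))
}

#' Intersect extracted features with a reference taxa list
#'
#' Order-preserving intersection by exact string match after whitespace
#' normalization (trim plus internal-whitespace collapse). The empty
#' intersection is allowed.
#'
#' @param features character vector of extracted feature ids.
#' @param reference_taxa character vector of reference lineage strings.
#' @return the features (original spelling, original order) present in
#'   the reference list.
#' @export
intersect_with_reference <- function(features, reference_taxa) {
  norm <- function(x) gsub("\\s+", " ", trimws(x))
  features[norm(features) %in% norm(reference_taxa)]
}
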