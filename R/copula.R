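#' Fit a kernel-density marginal model to one feature
#'
#' Gaussian KDE with rule-of-thumb (Silverman) bandwidth; a column with
#' zero variance collapses to a constant model. The model exposes a
#' monotone cdf and inverse cdf for the probability-integral transform.
#'
#' @param values numeric vector of at least 2 training values.
#' @return a `marginal_model` with `kind` (`"gaussian_kde"` or
#'   `"constant"`), `support_min`, `support_max`, `bandwidth` and the
#'   retained `training_values`.
#' @export
fit_marginal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("fit_marginal: need at least 2 values")
  if (anyNA(values)) stop("fit_marginal: NA values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(list(kind = "constant", value = rng[1],
                          support_min = rng[1], support_max = rng[2],
                          bandwidth = 0, training_values = values),
                     class = "marginal_model"))
  }
  bw <- stats::bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) bw <- diff(rng) / 100
  structure(list(kind = "gaussian_kde", support_min = rng[1],
                 support_max = rng[2], bandwidth = bw,
                 training_values = values),
            class = "marginal_model")
}

#' Marginal cumulative distribution function
#'
#' @param model a `marginal_model`.
#' @param x numeric vector of evaluation points.
#' @return `P(X <= x)` under the fitted marginal.
#' @export
marginal_cdf <- function(model, x) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$kind == "constant") return(as.numeric(x >= model$value))
  v <- model$training_values
  rowMeans(stats::pnorm(outer(x, v, "-") / model$bandwidth))
}

#' Marginal inverse cdf (quantile function)
#'
#' Constant models return the constant for every `u`; KDE models invert
#' the cdf by vectorized bisection on an interval extending ten
#' bandwidths past the observed support.
#'
#' @param model a `marginal_model`.
#' @param u probabilities in `[0, 1]`.
#' @return quantiles such that `marginal_cdf(model, q) ~= u`.
#' @export
marginal_icdf <- function(model, u) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$kind == "constant") return(rep(model$value, length(u)))
  v <- model$training_values
  h <- model$bandwidth
  lo <- rep(model$support_min - 10 * h, length(u))
  hi <- rep(model$support_max + 10 * h, length(u))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    cm <- rowMeans(stats::pnorm(outer(mid, v, "-") / h))
    below <- cm < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Fit a Gaussian copula to an OTU table
#'
#' Each feature is mapped to latent normal scores by the probit of its
#' marginal cdf (values clipped to `(delta, 1 - delta)` with
#' `delta = 1/(4n)` to keep scores finite). The latent correlation is the
#' sample correlation of the scores, shrunk toward the identity by
#' `lambda = min(0.5, p / (10 n))` and repaired to the nearest
#' positive-semidefinite correlation matrix when needed.
#'
#' @param table an `otu_table` (or plain matrix) with at least 2 samples.
#' @param enforce_min_max clip synthesized values to observed per-feature
#'   bounds (default `TRUE`).
#' @param enforce_rounding round synthesized values to the nearest
#'   integer (default `TRUE`).
#' @return a `copula_model` with `marginals`, `latent_corr` (shrunk,
#'   PSD), `empirical_corr` (pre-shrinkage score correlation) and
#'   `shrinkage`.
#' @export
fit_copula <- function(table, enforce_min_max = TRUE, enforce_rounding = TRUE) {
  X <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("fit_copula: need at least 2 samples")
  marginals <- lapply(seq_len(p), function(j) fit_marginal(X[, j]))
  names(marginals) <- colnames(X)
  delta <- 1 / (4 * n)
  Z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    u <- marginal_cdf(marginals[[j]], X[, j])
    Z[, j] <- stats::qnorm(pmin(pmax(u, delta), 1 - delta))
  }
  const <- vapply(marginals, function(m) m$kind == "constant", TRUE)
  S <- suppressWarnings(stats::cor(Z))
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  if (any(const)) { S[const, ] <- 0; S[, const] <- 0; diag(S) <- 1 }
  lambda <- min(0.5, p / (10 * n))
  C <- (1 - lambda) * S + lambda * diag(p)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE, do2eigen = TRUE)$mat)
  }
  dimnames(C) <- list(colnames(X), colnames(X))
  structure(list(marginals = marginals, latent_corr = C,
                 empirical_corr = S, shrinkage = lambda,
                 enforce_min_max = enforce_min_max,
                 enforce_rounding = enforce_rounding,
                 n_train = n),
            class = "copula_model")
}

#' Sample synthetic records from a fitted copula
#'
#' Draws latent multivariate-normal vectors with the model's latent
#' correlation, maps them through the normal cdf and each marginal's
#' inverse cdf, then (per the model flags) clips to the observed
#' per-feature bounds and rounds to the nearest integer.
#'
#' @param model a `copula_model` from [fit_copula()].
#' @param n number of samples to draw (`>= 1`).
#' @param seed RNG seed; the draw is deterministic given `(model, n, seed)`.
#' @param id_prefix prefix for generated sample ids.
#' @return an `otu_table` of `n` synthetic samples.
#' @export
sample_synthetic <- function(model, n, seed, id_prefix = "syn") {
  stopifnot(inherits(model, "copula_model"))
  if (n < 1) stop("sample_synthetic: n must be >= 1")
  p <- length(model$marginals)
  E <- eigen(model$latent_corr, symmetric = TRUE)
  A <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), p)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% t(A)
    U <- stats::pnorm(Z)
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      m <- model$marginals[[j]]
      x <- marginal_icdf(m, U[, j])
      if (model$enforce_min_max) x <- pmin(pmax(x, m$support_min), m$support_max)
      if (model$enforce_rounding) x <- round(x)
      X[, j] <- x
    }
    dimnames(X) <- list(sprintf("%s_%03d", id_prefix, seq_len(n)),
                        names(model$marginals))
    otu_table(X)
  })
}

#' Augmentation plan
#'
#' Per-specimen, per-condition sample totals after augmentation. Defaults
#' mirror the study layout: 59 stool, 63 biopsy and 68 saliva samples per
#' condition (190 per condition in total), with the copula for each CRC
#' specimen fitted on a seeded random subset of 20 real samples.
#'
#' @param target_totals named numeric, per-specimen per-condition totals.
#' @param crc_training_subset_size number of real CRC samples per specimen
#'   used to fit the synthesizer (all AP samples are always used).
#' @param seed RNG seed governing subset draws and sampling.
#' @return an `augmentation_plan`.
#' @export
augmentation_plan <- function(target_totals = c(stool = 59, biopsy = 63, saliva = 68),
                              crc_training_subset_size = 20,
                              seed = 1) {
  stopifnot(all(c("stool", "biopsy", "saliva") %in% names(target_totals)))
  structure(list(target_totals = target_totals,
                 crc_training_subset_size = crc_training_subset_size,
                 seed = seed),
            class = "augmentation_plan")
}

#' Augment a real dataset to the planned per-group totals
#'
#' For each `(condition, specimen)` group a copula is fitted on the real
#' samples of the group (for CRC, on a seeded random subset of
#' `crc_training_subset_size` samples per specimen) and synthetic samples
#' are generated in rounds of the training-set size until the group's
#' target total is reached (the last round is truncated). Real and
#' synthetic samples are returned together, flagged by provenance, with a
#' `round` metadata column (0 for real samples).
#'
#' @param table an `otu_table` of real samples.
#' @param meta matching sample metadata.
#' @param plan an [augmentation_plan()].
#' @return list with `table`, `meta` and a `counts` summary data.frame
#'   (per group: real, training, synthetic, total).
#' @export
augment_dataset <- function(table, meta, plan = augmentation_plan()) {
  validate_otu_table(table)
  validate_sample_meta(meta, table)
  stopifnot(inherits(plan, "augmentation_plan"))
  groups <- partition_otu(table, meta, by = c("condition", "specimen"))
  tabs <- list(); metas <- list(); summ <- list()
  seeds <- with_seed(plan$seed, sample.int(.Machine$integer.max, 2 * length(groups)))
  gi <- 0
  for (gname in names(groups)) {
    gi <- gi + 1
    grp <- groups[[gname]]
    cond <- grp$meta$condition[1]; spec <- grp$meta$specimen[1]
    n_real <- nrow(grp$table$counts)
    target <- plan$target_totals[[spec]]
    if (is.null(target)) stop("no target total for specimen: ", spec)
    if (target < n_real)
      stop("target total (", target, ") smaller than real count (", n_real,
           ") for group ", gname)
    train_idx <- seq_len(n_real)
    if (cond == "CRC" && n_real > plan$crc_training_subset_size) {
      train_idx <- sort(with_seed(seeds[2 * gi - 1],
                                  sample.int(n_real, plan$crc_training_subset_size)))
    }
    if (length(train_idx) < 2) stop("group ", gname, " has < 2 training samples")
    n_synth <- target - n_real
    tabs[[paste0(gname, ".real")]] <- grp$table$counts
    metas[[paste0(gname, ".real")]] <- cbind(grp$meta, round = 0L)
    if (n_synth > 0) {
      model <- fit_copula(subset_otu(grp$table, samples = train_idx))
      round_size <- length(train_idx)
      n_rounds <- ceiling(n_synth / round_size)
      round_seeds <- with_seed(seeds[2 * gi],
                               sample.int(.Machine$integer.max, n_rounds))
      made <- 0; r <- 0
      while (made < n_synth) {
        r <- r + 1
        nb <- min(round_size, n_synth - made)
        batch <- sample_synthetic(model, nb, seed = round_seeds[r],
                                  id_prefix = sprintf("syn_%s_%s_r%d", cond, spec, r))
        tabs[[sprintf("%s.syn%d", gname, r)]] <- batch$counts
        metas[[sprintf("%s.syn%d", gname, r)]] <- data.frame(
          sample_id = batch$sample_ids,
          patient_id = "synthetic",
          condition = cond, specimen = spec, provenance = "synthetic",
          round = r, stringsAsFactors = FALSE)
        made <- made + nb
      }
    }
    summ[[gname]] <- data.frame(condition = cond, specimen = spec,
                                real = n_real, training = length(train_idx),
                                synthetic = n_synth, total = target,
                                stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, tabs)
  out_meta <- do.call(rbind, metas)
  rownames(out_meta) <- NULL
  out_tab <- otu_table(counts)
  validate_sample_meta(out_meta, out_tab)
  list(table = out_tab, meta = out_meta,
       counts = {s <- do.call(rbind, summ); rownames(s) <- NULL; s})
}
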