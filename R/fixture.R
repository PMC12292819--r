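# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.DEFAULT_GROUP_SIZES <- c(AP.stool = 9, AP.biopsy = 13, AP.saliva = 12,
                          CRC.stool = 34, CRC.biopsy = 40, CRC.saliva = 40)

#' Fixture generator configuration
#'
#' Defines a seeded synthetic "ground truth" OTU dataset: a two-condition
#' (AP/CRC), three-specimen (stool/biopsy/saliva) count table with
#' heavy-tailed, zero-inflated counts and a configurable set of planted
#' differentially abundant taxa. Default group sizes mirror the study
#' layout (AP 9/13/12, CRC 34/40/40 for stool/biopsy/saliva).
#'
#' Counts are drawn as zero-inflated Poisson draws around per-taxon,
#' per-specimen log-normal baselines; samples from the same patient share
#' a latent offset, exposing intra-patient correlation.
#'
#' @param n_features number of taxa.
#' @param group_sizes named integer vector `condition.specimen -> count`.
#' @param n_planted number of planted differential taxa (`<= n_features`).
#' @param effect_size multiplicative abundance fold-change for planted
#'   taxa in their enriched condition (must be `> 0`; `1` means no signal).
#' @param zero_inflation probability a count is structurally zero, in `[0, 1)`.
#' @param dispersion standard deviation of the per-cell log-normal noise
#'   (overdispersion of the count law).
#' @param specimen_shift named numeric, per-specimen baseline
#'   log-abundance offsets.
#' @param base_log_mean grand mean of per-taxon log baselines.
#' @param feature_sd standard deviation of per-taxon log baselines.
#' @param patient_sd standard deviation of the shared per-patient offset.
#' @param seed mandatory RNG seed.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_features = 200,
                           group_sizes = .DEFAULT_GROUP_SIZES,
                           n_planted = 10,
                           effect_size = 4,
                           zero_inflation = 0.3,
                           dispersion = 0.7,
                           specimen_shift = c(stool = 0, biopsy = -0.5, saliva = 0.5),
                           base_log_mean = 3.5,
                           feature_sd = 1,
                           patient_sd = 0.3,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("fixture_config: seed is mandatory")
  if (n_planted > n_features)
    stop("n_planted (", n_planted, ") exceeds n_features (", n_features, ")")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)")
  keys <- strsplit(names(group_sizes), ".", fixed = TRUE)
  if (any(vapply(keys, length, 1L) != 2))
    stop("group_sizes names must be 'condition.specimen'")
  structure(list(n_features = n_features, group_sizes = group_sizes,
                 n_planted = n_planted, effect_size = effect_size,
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 specimen_shift = specimen_shift,
                 base_log_mean = base_log_mean, feature_sd = feature_sd,
                 patient_sd = patient_sd, seed = seed),
            class = "fixture_config")
}

#' Generate a seeded fixture dataset with planted differential taxa
#'
#' @param config a [fixture_config()].
#' @return list with `table` (an `otu_table`), `meta` (sample metadata)
#'   and `truth` (planted feature ids and per-taxon enriched condition).
#'   The same seed yields identical output.
#' @export
make_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    p <- config$n_features
    feat_ids <- sprintf("Taxon_%03d;Lineage_%03d", seq_len(p), seq_len(p))
    base <- stats::rnorm(p, config$base_log_mean, config$feature_sd)
    planted_idx <- sort(sample.int(p, config$n_planted))
    # alternate enrichment direction so neither condition is uniformly richer
    direction <- rep(c("CRC", "AP"), length.out = config$n_planted)

    gs <- config$group_sizes
    keys <- strsplit(names(gs), ".", fixed = TRUE)
    conds <- vapply(keys, `[[`, "", 1)
    specs <- vapply(keys, `[[`, "", 2)

    rows <- list(); metas <- list()
    # minimal patient pool per condition: each patient gives <= 1 sample per specimen
    for (cond in unique(conds)) {
      sel <- conds == cond
      n_pat <- max(gs[sel])
      pat_offset <- stats::rnorm(n_pat, 0, config$patient_sd)
      for (g in which(sel)) {
        n <- gs[g]; spec <- specs[g]
        pat <- seq_len(n)  # first n patients of the pool
        mu <- matrix(base, nrow = n, ncol = p, byrow = TRUE) +
          config$specimen_shift[[spec]] + pat_offset[pat]
        eff <- log(config$effect_size)
        for (k in seq_along(planted_idx)) {
          if (direction[k] == cond) mu[, planted_idx[k]] <- mu[, planted_idx[k]] + eff
        }
        lambda <- exp(mu + stats::rnorm(n * p, 0, config$dispersion))
        cnt <- matrix(stats::rpois(n * p, lambda), nrow = n)
        zero <- matrix(stats::runif(n * p) < config$zero_inflation, nrow = n)
        cnt[zero] <- 0
        ids <- sprintf("%s_%s_%02d", cond, spec, seq_len(n))
        rownames(cnt) <- ids
        rows[[names(gs)[g]]] <- cnt
        metas[[names(gs)[g]]] <- data.frame(
          sample_id = ids,
          patient_id = sprintf("%s_patient_%02d", cond, pat),
          condition = cond, specimen = spec, provenance = "real",
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- feat_ids
    meta <- do.call(rbind, metas)
    rownames(meta) <- NULL
    tab <- otu_table(counts)
    validate_sample_meta(meta, tab)
    list(table = tab, meta = meta,
         truth = list(planted_feature_ids = feat_ids[planted_idx],
                      direction = stats::setNames(direction, feat_ids[planted_idx])))
  })
}

#' Degrade a table into a correlation-free negative control
#'
#' Independently permutes each column and adds a small rounded jitter,
#' destroying inter-feature correlation while approximately preserving
#' the per-column marginals. Intended as a deliberately bad "synthesizer"
#' for exercising the quality gate.
#'
#' @param table an `otu_table`.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return a same-shape `otu_table` with suffixed sample ids.
#' @export
degrade_to_noise <- function(table, seed) {
  validate_otu_table(table)
  with_seed(seed, {
    cnt <- table$counts
    n <- nrow(cnt)
    out <- apply(cnt, 2, function(v) {
      v <- v[sample.int(n)]
      pmax(round(v + stats::rnorm(n, 0, 0.05 * (stats::sd(v) + 1e-8))), 0)
    })
    out <- matrix(out, nrow = n,
                  dimnames = list(paste0(table$sample_ids, "_noise"),
                                  table$feature_ids))
    otu_table(out)
  })
}
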