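# Shared builders and independent oracles for the suite.

# Tiny 3x2 table used across I/O tests.
tiny_table <- function() {
  otu_table(matrix(c(0, 2, 1, 5, 0, 1), nrow = 3,
                   dimnames = list(c("s1", "s2", "s3"), c("fA", "fB"))))
}

tiny_meta <- function() {
  sample_meta(sample_id = c("s1", "s2", "s3"),
              patient_id = c("p1", "p1", "p2"),
              condition = c("AP", "AP", "CRC"),
              specimen = c("stool", "biopsy", "saliva"))
}

# One-group fixture used for synthesis QC checks: 30 samples, 50 features,
# no planted signal.
qc_group_fixture <- function(seed) {
  make_fixture(fixture_config(n_features = 50, group_sizes = c(CRC.stool = 30),
                              n_planted = 0, seed = seed))$table
}

# A reduced net spec that keeps cross-validated trainings fast in unit tests.
small_net_spec <- function(...) {
  dense_net_spec(widths = c(16, 8, 1), epochs = 15, ...)
}

# Brute-force two-sample KS statistic over pooled breakpoints.
brute_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

# Brute-force chi-squared screening statistic (class totals vs prior).
brute_chi2 <- function(X, labels) {
  labels <- as.factor(labels)
  prior <- as.numeric(table(labels)) / length(labels)
  vapply(seq_len(ncol(X)), function(j) {
    obs <- tapply(X[, j], labels, sum)
    expd <- prior * sum(obs)
    sum((obs - expd)^2 / expd)
  }, 0)
}

# Exhaustive Shapley values over all 2^p subsets with a single background row.
exhaustive_shap <- function(f, x, bg) {
  p <- length(x)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- unlist(subsets[r, ])
      if (S[i]) next
      w <- factorial(sum(S)) * factorial(p - sum(S) - 1) / factorial(p)
      z0 <- ifelse(S, x, bg)
      z1 <- z0; z1[i] <- x[i]
      phi[i] <- phi[i] + w * (f(rbind(z1)) - f(rbind(z0)))
    }
  }
  phi
}

# Metadata shaped like the augmented study layout (190 per condition:
# 59 stool / 63 biopsy / 68 saliva), without running the synthesizer.
augmented_shape_meta <- function() {
  sizes <- c(stool = 59, biopsy = 63, saliva = 68)
  recs <- list()
  for (cond in c("AP", "CRC")) for (sp in names(sizes)) {
    ids <- sprintf("%s_%s_%02d", cond, sp, seq_len(sizes[[sp]]))
    recs[[paste(cond, sp)]] <- data.frame(
      sample_id = ids, patient_id = "px", condition = cond, specimen = sp,
      provenance = "real", stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, recs)
  rownames(meta) <- NULL
  meta
}

# A random table matching a metadata frame (one row per sample).
table_for_meta <- function(meta, n_features = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nrow(meta) * n_features, 5), nrow(meta),
              dimnames = list(meta$sample_id, paste0("F", seq_len(n_features))))
  otu_table(m)
}
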