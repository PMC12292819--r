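test_that("chi-squared screening matches the brute-force statistic", {
  set.seed(2)
  X <- matrix(rpois(40 * 10, 5), 40)
  y <- rep(c("a", "b"), each = 20)
  # saturation
  expect_identical(as.integer(screen_features_chi2(X, y, 10)), 1:10)
  expect_identical(as.integer(screen_features_chi2(X, y, 99)), 1:10)
  # a single feature that is informative
  X2 <- X; X2[, 4] <- ifelse(y == "b", rpois(40, 40), 0)
  expect_identical(as.integer(screen_features_chi2(X2, y, 1)), 4L)
  # full agreement with the independent oracle
  got <- attr(screen_features_chi2(X2, y, 3), "statistic")
  expect_equal(unname(got), brute_chi2(X2, y), tolerance = 1e-12)
  expect_error(screen_features_chi2(-X, y, 2), "negative")
  expect_error(screen_features_chi2(X, rep("a", 40), 2), "single class")
})

test_that("chi-squared screening keeps exactly 500 of a wider table", {
  set.seed(8)
  X <- matrix(rpois(20 * 600, 3), 20)
  y <- rep(c("r", "s"), each = 10)
  expect_length(screen_features_chi2(X, y, 500), 500)
})

test_that("SVC random search respects its boxes and ordering", {
  set.seed(14)
  X <- matrix(rnorm(60 * 4), 60)
  y <- rep(c("a", "b"), each = 30)
  one <- tune_polynomial_svc(X, y, n_trials = 1, seed = 3)
  expect_identical(nrow(one$trials), 1L)
  expect_identical(one$C, one$trials$C[1])
  res <- tune_polynomial_svc(X + ifelse(y == "b", 3, 0), y, n_trials = 15, seed = 4)
  expect_true(all(res$trials$C >= 0.01 & res$trials$C <= 1000))
  expect_true(all(res$trials$gamma >= 1e-4 & res$trials$gamma <= 100))
  expect_gte(res$cv_accuracy, min(res$trials$cv_accuracy))
  expect_equal(res$cv_accuracy, max(res$trials$cv_accuracy))
})

test_that("adversarial report is near chance on identically distributed data", {
  tab <- qc_group_fixture(61)
  # a random split of real data labelled real-vs-synthetic: indistinguishable
  set.seed(10)
  half <- sample.int(nrow(tab$counts), nrow(tab$counts) / 2)
  rep_ <- adversarial_report(tab$counts[half, ], tab$counts[-half, ],
                             k = 50, seed = 2)
  expect_true(all(abs(rep_$metrics$accuracy - 0.5) <= 0.15))
  mets <- as.matrix(rep_$metrics[, c("accuracy", "precision", "recall", "f1")])
  expect_true(all(mets >= 0 & mets <= 1))
  expect_identical(rep_$screened_feature_count, 50L)
  expect_error(adversarial_report(tab$counts[0, ], tab), "empty")
})

test_that("the KS battery matches a brute-force ECDF oracle and edge cases", {
  tab <- qc_group_fixture(62)
  same <- ks_battery(tab, tab)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_adjusted == 1))
  expect_equal(sum(same$reject), 0)

  # disjoint supports give statistic 1
  x <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f"))
  y <- matrix(c(10, 11, 12, 13), 4, 1, dimnames = list(NULL, "f"))
  expect_equal(ks_battery(x, y)$statistic, 1)

  # brute-force oracle on random 10-value columns
  set.seed(77)
  for (i in 1:10) {
    a <- matrix(sample(0:5, 10, TRUE), 10, 1, dimnames = list(NULL, "f"))
    b <- matrix(sample(0:5, 10, TRUE), 10, 1, dimnames = list(NULL, "f"))
    expect_equal(ks_battery(a, b)$statistic, brute_ks_stat(a, b), tolerance = 1e-12)
  }
  expect_error(ks_battery(x, cbind(y, y)), "mismatched")
})

test_that("Bonferroni adjustment is monotone in the number of tests", {
  p_raw <- 0.004
  adj <- function(n) min(1, p_raw * n)
  ns <- c(1, 5, 10, 50, 500)
  expect_true(all(diff(vapply(ns, adj, 0)) >= 0))
  # and in the battery: rejections never increase when features are added
  tab <- qc_group_fixture(63)
  syn <- sample_synthetic(fit_copula(tab), 30, seed = 4)
  r10 <- ks_battery(subset_otu(tab, features = 1:10),
                    subset_otu(syn, features = 1:10))
  r50 <- ks_battery(tab, syn)
  shared <- intersect(r10$feature_id, r50$feature_id)
  expect_true(all(r50$p_adjusted[match(shared, r50$feature_id)] >=
                  r10$p_adjusted[match(shared, r10$feature_id)]))
})

test_that("column similarity statistics obey closed forms", {
  set.seed(5)
  X <- matrix(rpois(20 * 6, 9), 20)
  idcols <- function(m) {colnames(m) <- paste0("F", 1:6); m}
  X <- idcols(X)
  id <- column_similarity(X, X)
  expect_equal(unname(id$aggregate[c("mean_difference", "std_difference", "mse")]),
               c(0, 0, 0))
  expect_equal(unname(id$aggregate["spearman_correlation"]), 1)
  sh <- column_similarity(X, X + 3)
  expect_equal(unname(sh$aggregate["mean_difference"]), 3)
  expect_equal(unname(sh$aggregate["std_difference"]), 0)
  # reversed strictly monotone pairing has Spearman -1
  a <- matrix(1:10, 10, 1); b <- matrix(10:1, 10, 1)
  expect_equal(unname(column_similarity(a, b)$aggregate["spearman_correlation"]), -1)
  expect_error(column_similarity(X, X[1:5, ]), "shape mismatch")
})

test_that("hard-example retention equals the set-logic definition", {
  tab <- qc_group_fixture(64)
  n <- nrow(tab$counts)
  expect_equal(sum(retain_hard_synthetic(tab, rep(0.99, n),
                                         list(margin = 0.2, include_misclassified = TRUE))$retained), 0)
  expect_equal(sum(retain_hard_synthetic(tab, rep(0.5, n))$retained), n)
  set.seed(31)
  sc <- runif(n)
  got <- retain_hard_synthetic(tab, sc, list(margin = 0.1, include_misclassified = TRUE))
  expect_identical(got$retained, sc < 0.5 | abs(sc - 0.5) < 0.1)
  expect_identical(got$table$counts, tab$counts[got$retained, , drop = FALSE])
  expect_error(retain_hard_synthetic(tab, sc[-1]), "scores")
})
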