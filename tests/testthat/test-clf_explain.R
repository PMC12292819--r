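test_that("stratified split hits the ratio per stratum and is seeded", {
  meta <- augmented_shape_meta()
  # drop the extraction-subset analogue: use the 172-per-condition remainder
  tab <- table_for_meta(meta)
  parts <- select_extraction_subset(tab, meta, seed = 1)
  rem <- parts$remainder
  sp <- stratified_split(rem$table, rem$meta, ratio = 0.8, seed = 9)
  expect_length(sp$holdout_ids, 68)   # round(0.2 * 53/57/62) summed over 6 strata
  expect_length(sp$train_ids, 344 - 68)
  key <- paste(rem$meta$condition, rem$meta$specimen)
  for (k in unique(key)) {
    ids <- rem$meta$sample_id[key == k]
    nh <- sum(ids %in% sp$holdout_ids)
    expect_lte(abs(nh - 0.2 * length(ids)), 1)
  }
  sp2 <- stratified_split(rem$table, rem$meta, ratio = 0.8, seed = 9)
  expect_identical(sp, sp2)
  none <- stratified_split(rem$table, rem$meta, ratio = 1, seed = 1)
  expect_length(none$holdout_ids, 0)
  small <- rem$meta[1:4, ]
  expect_error(stratified_split(subset_otu(rem$table, samples = 1:4), small,
                                ratio = 0.8, seed = 1), "only")
})

test_that("model comparison shares folds, averages correctly, and separates signal", {
  fx <- make_fixture(fixture_config(n_features = 50, seed = 70))
  y <- factor(fx$meta$condition, levels = c("AP", "CRC"))
  cv <- compare_models_cv(fx$table$counts, y, folds = 5, seed = 3)
  expect_identical(rownames(cv$fold_accuracy),
                   c("polynomial_svc", "xgboost", "random_forest"))
  expect_equal(unname(cv$mean_accuracy), unname(rowMeans(cv$fold_accuracy)))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_identical(cv$best_model, names(which.max(cv$mean_accuracy)))
  # planted signal at effect 4 is separable by the tree models
  expect_gte(max(cv$mean_accuracy), 0.7)
  expect_error(compare_models_cv(fx$table$counts[1:12, ], y[1:12], folds = 10),
               "fewer samples")
})

test_that("holdout evaluation produces a sound ROC and near-chance nulls", {
  fx <- make_fixture(fixture_config(n_features = 40, seed = 71))
  y <- factor(fx$meta$condition, levels = c("AP", "CRC"))
  sp <- stratified_split(fx$table, fx$meta, ratio = 0.8, seed = 2)
  tr <- which(fx$table$sample_ids %in% sp$train_ids)
  ho <- which(fx$table$sample_ids %in% sp$holdout_ids)
  rep_ <- fit_final_and_evaluate("xgboost", fx$table$counts[tr, ], y[tr],
                                 fx$table$counts[ho, ], y[ho], seed = 4)
  expect_equal(rep_$roc$fpr[1], 0); expect_equal(rep_$roc$tpr[1], 0)
  expect_equal(tail(rep_$roc$fpr, 1), 1); expect_equal(tail(rep_$roc$tpr, 1), 1)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  expect_identical(rep_$class_report$class, c("AP", "CRC"))
  expect_equal(sum(rep_$class_report$support), length(ho))
  # leakage-control harness: evaluating on training data mirrors training accuracy
  rep_leak <- fit_final_and_evaluate("xgboost", fx$table$counts[tr, ], y[tr],
                                     fx$table$counts[tr, ], y[tr], seed = 4)
  expect_gte(rep_leak$accuracy, 0.95)
  # random labels give near-chance holdout accuracy (5 seeds)
  null_acc <- vapply(1:5, function(s) {
    set.seed(s)
    yr <- factor(sample(c("AP", "CRC"), nrow(fx$table$counts), TRUE),
                 levels = c("AP", "CRC"))
    fit_final_and_evaluate("random_forest", fx$table$counts[tr, ], yr[tr],
                           fx$table$counts[ho, ], yr[ho], seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(null_acc) - 0.5), 0.15)
  expect_error(fit_final_and_evaluate("xgboost", fx$table$counts[tr, ], y[tr],
                                      fx$table$counts[0, ], y[0]), "empty")
})

test_that("tree-exact attributions satisfy additivity", {
  set.seed(6)
  n <- 150
  x1 <- rnorm(n)
  X <- cbind(f1 = x1, f2 = x1, f3 = rnorm(n), f4 = rnorm(n))
  y <- as.integer(x1 + 0.5 * X[, "f3"] > 0)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, colsample_bynode = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = 30, verbose = 0)
  rep_ <- shap_attributions(bst, X, method = "tree_exact")
  expect_lte(max(abs(rep_$additivity_residuals)), 1e-6)
  expect_identical(dim(rep_$values), dim(X))
  expect_error(shap_attributions(lm(y ~ X), X, method = "tree_exact"),
               "tree")
})

test_that("sampled attributions match closed forms and exhaustive enumeration", {
  # one-feature model: the single feature gets f(x) - base, others 0
  f1 <- function(M) 2 * M[, 1] + 1
  X <- matrix(c(3, 0, 0, -1, 5, 2), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(0, 1, 3)
  rep1 <- shap_attributions(NULL, X, background = bg,
                            method = "permutation_sampled", predict_fun = f1,
                            n_perm = 10, seed = 1)
  expect_equal(unname(rep1$values[, 1]), 2 * X[, 1], tolerance = 1e-12)
  expect_equal(unname(rep1$values[, 2]), c(0, 0))
  expect_equal(rep1$base_value, 1)
  expect_equal(unname(rep1$additivity_residuals), c(0, 0), tolerance = 1e-12)

  # exhaustive-Shapley oracle on a nonlinear model, p = 6
  set.seed(7)
  p <- 6
  f <- function(M) sin(M[, 1]) + M[, 2] * M[, 3] + 0.5 * M[, 4]^2 - M[, 5]
  x <- rnorm(p); bg <- matrix(rnorm(p, 0, 0.2), 1)
  got <- shap_attributions(NULL, matrix(x, 1), background = bg,
                           method = "permutation_sampled", predict_fun = f,
                           n_perm = 300, seed = 2)
  want <- exhaustive_shap(f, x, as.numeric(bg))
  expect_equal(unname(got$values[1, ]), want, tolerance = 0.05)
  expect_lt(max(abs(got$additivity_residuals)), 1e-10)

  # symmetry: exchangeable features in a constructed model get equal values
  fsym <- function(M) M[, 1] * M[, 2] + M[, 1] + M[, 2]
  xs <- c(1.3, 1.3, -2)
  sym <- shap_attributions(NULL, matrix(xs, 1), background = matrix(0, 1, 3),
                           method = "permutation_sampled", predict_fun = fsym,
                           n_perm = 100, seed = 3)
  expect_equal(unname(sym$values[1, 1]), unname(sym$values[1, 2]),
               tolerance = 1e-10)
})

test_that("per-specimen sub-reports partition the holdout and exports are complete", {
  fx <- make_fixture(fixture_config(n_features = 12, seed = 73))
  y <- factor(fx$meta$condition, levels = c("AP", "CRC"))
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.2, nthread = 1),
    data = xgboost::xgb.DMatrix(fx$table$counts, label = as.integer(y == "CRC"),
                                nthread = 1),
    nrounds = 20, verbose = 0)
  rep_ <- shap_attributions(bst, fx$table$counts, method = "tree_exact",
                            meta = fx$meta)
  expect_setequal(names(rep_$by_specimen), c("stool", "biopsy", "saliva"))
  expect_setequal(unlist(lapply(rep_$by_specimen, `[[`, "sample_ids")),
                  fx$table$sample_ids)
  out <- export_plot_data(rep_, fx$table$counts, meta = fx$meta,
                          dir = withr::local_tempdir())
  expect_equal(nrow(out$summary), 12)
  expect_equal(nrow(out$force), nrow(fx$table$counts) * 12)
  expect_equal(nrow(out$beeswarm), nrow(fx$table$counts) * 12)
  # force layout: all AP first, then all CRC
  conds <- out$force$condition[!duplicated(out$force$sample_position)]
  expect_identical(conds, sort(conds))
  # top-ranked feature equals the hand-computed argmax of mean |value|
  ma <- colMeans(abs(rep_$values))
  expect_identical(out$summary$feature_id[1], names(which.max(ma)))
})
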