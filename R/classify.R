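.MODELS <- c("polynomial_svc", "xgboost", "random_forest")

#' Specimen-balanced train/holdout split
#'
#' Seeded per-stratum (condition x specimen) split; each stratum
#' contributes a holdout fraction within one sample of the requested
#' ratio.
#'
#' @param table an `otu_table`.
#' @param meta matching metadata.
#' @param ratio training fraction (default 0.8, i.e. an 80:20 split).
#' @param seed RNG seed.
#' @param min_stratum smallest allowed stratum size (default 5; ignored
#'   when `ratio` is 0 or 1).
#' @return a `split_plan`: `train_ids`, `holdout_ids`, `ratio`, `seed`.
#' @export
stratified_split <- function(table, meta, ratio = 0.8, seed = 1, min_stratum = 5) {
  validate_otu_table(table)
  validate_sample_meta(meta, table)
  meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
  key <- paste(meta$condition, meta$specimen, sep = ".")
  holdout <- character(0)
  with_seed(seed, {
    for (k in unique(key)) {
      ids <- meta$sample_id[key == k]
      if (ratio > 0 && ratio < 1 && length(ids) < min_stratum)
        stop("stratum ", k, " has only ", length(ids), " samples")
      n_hold <- round((1 - ratio) * length(ids))
      if (n_hold > 0) holdout <- c(holdout, sample(ids, n_hold))
    }
  })
  structure(list(train_ids = setdiff(table$sample_ids, holdout),
                 holdout_ids = table$sample_ids[table$sample_ids %in% holdout],
                 ratio = ratio, seed = seed),
            class = "split_plan")
}

# Condition labels as a factor with CRC as the positive (second) level.
condition_factor <- function(x) factor(as.character(x), levels = c("AP", "CRC"))

fit_clf <- function(model, X, y, seed, svc_params = NULL,
                    xgb_params = list(nrounds = 300, max_depth = 4, eta = 0.1)) {
  y <- condition_factor(y)
  with_seed(seed, switch(model,
    polynomial_svc = {
      if (is.null(svc_params)) svc_params <- list(C = 1, gamma = 1 / ncol(X))
      suppressWarnings(e1071::svm(x = X, y = y, kernel = "polynomial",
                                  cost = svc_params$C, gamma = svc_params$gamma,
                                  scale = FALSE, probability = TRUE))
    },
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = xgb_params$max_depth, eta = xgb_params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y == "CRC"), nthread = 1),
      nrounds = xgb_params$nrounds, verbose = 0),
    random_forest = randomForest::randomForest(x = X, y = y),
    stop("unknown model: ", model)))
}

# P(CRC) scores from any of the three fitted classifiers.
predict_crc_score <- function(fit, X) {
  if (inherits(fit, "svm")) {
    pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
    return(unname(pr[, "CRC"]))
  }
  if (inherits(fit, "xgb.Booster")) return(unname(predict(fit, X)))
  if (inherits(fit, "randomForest")) return(unname(predict(fit, X, type = "prob")[, "CRC"]))
  stop("unsupported model object: ", paste(class(fit), collapse = "/"))
}

#' Ten-fold cross-validated comparison of three classifiers
#'
#' Polynomial-kernel SVC, gradient-boosted trees (300 trees, depth 4,
#' learning rate 0.1) and random forest are evaluated on identical
#' stratified folds; the best model is the one with the highest mean
#' accuracy, ties going to the listed order.
#'
#' @param X feature matrix or `otu_table`.
#' @param labels condition labels (`AP`/`CRC`).
#' @param folds number of folds (default 10).
#' @param seed RNG seed (folds and per-fold fit seeds).
#' @param svc_params optional SVC `C`/`gamma` (e.g. from
#'   [tune_polynomial_svc()]).
#' @return a `cv_result`: `fold_accuracy` (models x folds),
#'   `mean_accuracy` and `best_model`.
#' @export
compare_models_cv <- function(X, labels, folds = 10, seed = 1, svc_params = NULL) {
  X <- as_count_matrix(X)
  y <- condition_factor(labels)
  if (min(table(y)) < folds) stop("compare_models_cv: fewer samples per class than folds")
  fold <- stratified_folds(y, folds, seed)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max, folds))
  acc <- matrix(0, length(.MODELS), folds, dimnames = list(.MODELS, NULL))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (m in .MODELS) {
      fit <- fit_clf(m, X[tr, , drop = FALSE], y[tr], fold_seeds[f], svc_params)
      sc <- predict_crc_score(fit, X[!tr, , drop = FALSE])
      acc[m, f] <- mean((sc > 0.5) == (y[!tr] == "CRC"))
    }
  }
  mean_acc <- rowMeans(acc)
  structure(list(fold_accuracy = acc, mean_accuracy = mean_acc,
                 best_model = .MODELS[which.max(mean_acc)]),
            class = "cv_result")
}

#' Retrain the selected model and evaluate it once on the holdout
#'
#' The chosen classifier is refit from scratch on the full training
#' subset and evaluated a single time on the held-out samples: accuracy,
#' ROC curve (positive class CRC), area under the ROC, and per-class
#' precision/recall/F1.
#'
#' @param best_model one of `"polynomial_svc"`, `"xgboost"`,
#'   `"random_forest"` (e.g. `cv_result$best_model`).
#' @param train_X,train_labels training subset.
#' @param holdout_X,holdout_labels holdout subset (nonempty).
#' @param seed RNG seed for the refit.
#' @param svc_params optional SVC parameters.
#' @return a `holdout_report`: `accuracy`, `roc` (fpr/tpr/threshold),
#'   `auc`, `class_report`, `scores`, and the fitted `model`.
#' @export
fit_final_and_evaluate <- function(best_model, train_X, train_labels,
                                   holdout_X, holdout_labels, seed = 1,
                                   svc_params = NULL) {
  train_X <- as_count_matrix(train_X); holdout_X <- as_count_matrix(holdout_X)
  if (nrow(holdout_X) == 0) stop("fit_final_and_evaluate: empty holdout")
  y_tr <- condition_factor(train_labels)
  y_ho <- condition_factor(holdout_labels)
  fit <- fit_clf(best_model, train_X, y_tr, seed, svc_params)
  sc <- predict_crc_score(fit, holdout_X)
  pred <- factor(ifelse(sc > 0.5, "CRC", "AP"), levels = levels(y_ho))
  roc_obj <- pROC::roc(response = y_ho, predictor = sc,
                       levels = c("AP", "CRC"), direction = "<", quiet = TRUE)
  ord <- order(1 - roc_obj$specificities, roc_obj$sensitivities)
  roc_df <- data.frame(fpr = (1 - roc_obj$specificities)[ord],
                       tpr = roc_obj$sensitivities[ord],
                       threshold = roc_obj$thresholds[ord])
  class_report <- do.call(rbind, lapply(levels(y_ho), function(cl) {
    m <- binary_metrics(y_ho, pred, cl)
    data.frame(class = cl, precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], support = sum(y_ho == cl), row.names = NULL)
  }))
  structure(list(best_model = best_model, accuracy = mean(pred == y_ho),
                 roc = roc_df, auc = as.numeric(pROC::auc(roc_obj)),
                 class_report = class_report, scores = sc, model = fit),
            class = "holdout_report")
}
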