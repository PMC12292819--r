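test_that("extraction subset is balanced, seeded, and partitions the data", {
  meta <- augmented_shape_meta()
  tab <- table_for_meta(meta)
  parts <- select_extraction_subset(tab, meta, fraction = 0.10, seed = 6)
  expect_equal(unname(table(parts$subset$meta$condition)[c("AP", "CRC")]),
               c(18L, 18L), ignore_attr = TRUE)
  expect_true(all(table(parts$subset$meta$condition, parts$subset$meta$specimen) == 6))
  expect_equal(unname(table(parts$remainder$meta$condition)[c("AP", "CRC")]),
               c(172L, 172L), ignore_attr = TRUE)
  # disjoint + exhaustive
  expect_length(intersect(parts$subset$meta$sample_id,
                          parts$remainder$meta$sample_id), 0)
  expect_setequal(c(parts$subset$meta$sample_id, parts$remainder$meta$sample_id),
                  meta$sample_id)
  # fraction 0 is a no-op
  p0 <- select_extraction_subset(tab, meta, fraction = 0, seed = 1)
  expect_equal(nrow(p0$subset$meta), 0)
  expect_equal(nrow(p0$remainder$meta), nrow(meta))
  # quota larger than a specimen group errors
  small <- meta[meta$specimen != "stool" | meta$condition != "AP", ]
  small <- rbind(small, meta[meta$specimen == "stool" & meta$condition == "AP", ][1:2, ])
  tab2 <- table_for_meta(small)
  expect_error(select_extraction_subset(tab2, small, fraction = 0.10, seed = 1),
               "quota")
})

test_that("the dense net trains to high accuracy on a separable toy, deterministically", {
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400), 200, 2)
    y <- as.integer(X[, 1] + X[, 2] > 0)
    net <- train_dense_net(X, y, dense_net_spec(seed = s))
    tail(net$history$accuracy, 1)
  }, 0)
  expect_true(all(accs >= 0.95))
  set.seed(1); X <- matrix(rnorm(200), 100, 2); y <- as.integer(X[, 1] > 0)
  n1 <- train_dense_net(X, y, dense_net_spec(seed = 42))
  n2 <- train_dense_net(X, y, dense_net_spec(seed = 42))
  expect_identical(n1$weights, n2$weights)
  expect_error(train_dense_net(X, rep(1, 100)), "constant")
  expect_error(train_dense_net(X, rep(c(1, 2), 50)), "binary")
})

test_that("activation sweep is paired across variants and averages correctly", {
  set.seed(20)
  X <- matrix(rnorm(60 * 4), 60)
  y <- as.integer(X[, 1] - X[, 2] + rnorm(60, 0, 0.3) > 0)
  sw <- activation_sweep(X, y, activations = c("relu", "relu", "gelu"),
                         spec = small_net_spec(), folds = 5, seed = 2)
  # identical variant listed twice gives identical accuracy (shared folds/seeds)
  expect_identical(sw$results$mean_accuracy[1], sw$results$mean_accuracy[2])
  expect_true(all(sw$results$mean_accuracy >= 0 & sw$results$mean_accuracy <= 1))
  expect_identical(sw$best, sw$results$activation[which.max(sw$results$mean_accuracy)])
  expect_error(activation_sweep(X[1:6, ], y[1:6], folds = 10), "fewer samples")
})

test_that("all four hidden activations train and predict", {
  set.seed(4)
  X <- matrix(rnorm(80 * 3), 80)
  y <- as.integer(X[, 1] > 0)
  for (act in c("relu", "leaky_relu", "softmax", "gelu")) {
    net <- train_dense_net(X, y, small_net_spec(activation = act, seed = 5))
    p <- predict(net, X)
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), info = act)
  }
})

test_that("LRP-epsilon satisfies its closed forms, conservation and symmetry", {
  # single linear layer, zero bias: R_i = x_i w_i summing to the logit
  w <- c(0.5, -1.2, 2)
  net <- structure(list(weights = list(matrix(w, 3, 1)), biases = list(0),
                        activation = "relu", alpha = 0.01),
                   class = "dense_net")
  x <- c(1, 2, -0.5)
  R <- lrp_epsilon(net, x, lrp_config(epsilon = 1e-12))
  expect_equal(unname(R), x * w, tolerance = 1e-6)
  expect_equal(sum(R), sum(x * w), tolerance = 1e-9)

  # conservation on random zero-bias two-layer nets
  for (i in 1:20) {
    set.seed(i)
    net <- structure(list(weights = list(matrix(rnorm(20), 5, 4),
                                         matrix(rnorm(4), 4, 1)),
                          biases = list(numeric(4), numeric(1)),
                          activation = "leaky_relu", alpha = 0.01),
                     class = "dense_net")
    x <- rnorm(5)
    R <- lrp_epsilon(net, x, lrp_config(epsilon = 1e-9))
    logit <- predict(net, matrix(x, 1), type = "logit")
    expect_lt(abs(sum(R) - logit) / max(abs(logit), 1e-12), 1e-6)
  }

  # duplicated input feature with duplicated weights gets equal relevance
  set.seed(3)
  W1 <- matrix(rnorm(12), 4, 3); W1[2, ] <- W1[1, ]
  net <- structure(list(weights = list(W1, matrix(rnorm(3), 3, 1)),
                        biases = list(numeric(3), numeric(1)),
                        activation = "relu", alpha = 0.01),
                   class = "dense_net")
  x <- c(0.7, 0.7, -1, 2)
  R <- lrp_epsilon(net, x, lrp_config(epsilon = 1e-9))
  expect_equal(R[1], R[2], tolerance = 1e-9)

  # permutation invariance: permuting inputs permutes relevances
  perm <- c(3, 1, 4, 2)
  netp <- net; netp$weights[[1]] <- net$weights[[1]][perm, ]
  Rp <- lrp_epsilon(netp, x[perm], lrp_config(epsilon = 1e-9))
  expect_equal(unname(Rp), unname(R[perm]), tolerance = 1e-12)

  expect_error(lrp_epsilon(net, x[1:2]), "input length")
})

test_that("cross-validated extraction ranks all features and recovers planted taxa", {
  fx <- make_fixture(fixture_config(n_features = 60, seed = 90))
  y <- factor(fx$meta$condition, levels = c("AP", "CRC"))
  ext <- cross_validated_extraction(fx$table, y, folds = 5, k = 60, seed = 2)
  # saturation: every feature returned, ranked
  expect_length(ext$top_features, 60)
  expect_setequal(ext$top_features, fx$table$feature_ids)
  expect_identical(ext$relevance$rank, seq_len(60L))
  expect_true(all(diff(ext$relevance$score) <= 0))
  expect_length(ext$fold_accuracy, 5)
  expect_equal(ext$mean_accuracy, mean(ext$fold_accuracy))
  # planted-signal recovery at the unit-test scale
  hits <- sum(fx$truth$planted_feature_ids %in% ext$relevance$feature_id[1:15])
  expect_gte(hits, 8)
  expect_error(cross_validated_extraction(fx$table, y, k = 999), "exceeds")
})

test_that("the default extraction width returns exactly 64 features", {
  fx <- make_fixture(fixture_config(n_features = 70, seed = 91))
  y <- factor(fx$meta$condition, levels = c("AP", "CRC"))
  ext <- cross_validated_extraction(fx$table, y, spec = small_net_spec(),
                                    folds = 4, seed = 3)
  expect_length(ext$top_features, 64)
})

test_that("reference intersection is order-preserving and whitespace-robust", {
  f <- c("Fam;GenusA", "Fam;GenusB", "Other;Thing")
  expect_identical(intersect_with_reference(f, f), f)
  expect_length(intersect_with_reference(f, c("X", "Y")), 0)
  expect_identical(intersect_with_reference(f, c("  Fam;GenusB ", "Other;Thing")),
                   c("Fam;GenusB", "Other;Thing"))
  # random set oracle
  set.seed(12)
  for (i in 1:5) {
    a <- unique(replicate(12, paste(sample(letters, 3), collapse = "")))
    b <- unique(replicate(12, paste(sample(letters, 3), collapse = "")))
    expect_setequal(intersect_with_reference(a, b), intersect(a, b))
  }
})
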