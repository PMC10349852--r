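# Small deterministic pair datasets for harness tests.
toy_dataset <- function(n = 40, p = 5, noise = 0, seed = 1,
                        target_fun = function(X) 2 * X[, 1]) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  colnames(X) <- paste0("a_f", seq_len(p))
  d <- tibble::as_tibble(X)
  d$arene_id <- sprintf("m%02d", rep(seq_len(ceiling(n / 3)), each = 3)[1:n])
  d$target <- target_fun(X) + stats::rnorm(n, 0, noise)
  d
}

test_that("ridge recovers a noiseless linear map through leave-one-out", {
  d <- toy_dataset(n = 40, p = 5, noise = 0)
  rep_ <- loo_evaluate(d, "ridge", seed = 1, augment = FALSE)
  expect_gte(rep_$pearson_r, 0.999)
  expect_lte(rep_$mae, 1e-6)
  lin <- loo_evaluate(d, "linear", seed = 1, augment = FALSE)
  expect_lte(lin$mae, 1e-8)
})

test_that("pure-noise targets yield near-zero correlation", {
  rs <- sapply(1:3, function(s) {
    d <- toy_dataset(n = 200, p = 5, seed = s,
                     target_fun = function(X) rep(0, nrow(X)))
    d$target <- withr::with_seed(100 + s, stats::rnorm(200))
    loo_evaluate(d, "ridge", seed = s, augment = FALSE)$pearson_r
  })
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("constant targets flag an undefined Pearson R but a valid MAE", {
  d <- toy_dataset(n = 12, p = 3)
  d$target <- 1.5
  expect_warning(rep_ <- loo_evaluate(d, "ridge", seed = 1, augment = FALSE),
                 "undefined")
  expect_true(is.nan(rep_$pearson_r))
  expect_lt(rep_$mae, 1e-6)   # mean-predicting limit of ridge
})

test_that("unknown algorithms are rejected by the registry", {
  d <- toy_dataset(n = 10)
  expect_error(loo_evaluate(d, "neural_net"), "unknown algorithm")
})

test_that("evaluation is deterministic for a fixed seed", {
  syn <- generate_synthetic_dataset(synthetic_config(n_arenes = 10, seed = 3))
  r1 <- loo_evaluate(syn$data, "extra_trees", seed = 7)
  r2 <- loo_evaluate(syn$data, "extra_trees", seed = 7)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$config_hash, r2$config_hash)
})

test_that("algorithm comparison ranks by Pearson R with MAE tie-breaks", {
  syn <- generate_synthetic_dataset(synthetic_config(n_arenes = 12, seed = 5))
  cmp <- compare_algorithms(syn$data, c("ridge", "knn"), seed = 1)
  tbl <- glance(cmp)
  expect_equal(nrow(tbl), 2)
  expect_true(all(diff(tbl$pearson_r) <= 0))
  expect_equal(tbl$rank, 1:2)
})

test_that("tree ensembles beat linear models on threshold ground truth", {
  syn <- generate_synthetic_dataset(
    synthetic_config(n_pairs = 90, noise_sd = 0.05, nonlinear = TRUE,
                     seed = 21))
  cmp <- glance(compare_algorithms(syn$data, c("extra_trees", "ridge"),
                                   seed = 1))
  expect_identical(cmp$algorithm[1], "extra_trees")
})

test_that("greedy forward selection finds the generating feature first", {
  d <- toy_dataset(n = 60, p = 6, noise = 0.05, seed = 2,
                   target_fun = function(X) 3 * X[, 4])
  sel <- greedy_feature_selection(d, "ridge", seed = 1, augment = FALSE)
  expect_identical(sel$features[1], "a_f4")
  expect_true(all(diff(sel$trajectory$pearson_r) >= -1e-12))
  # noise features should not be retained at the default tolerance
  expect_lte(length(sel$features), 3)
})

test_that("impurity importances are normalized and restricted to trees", {
  syn <- generate_synthetic_dataset(synthetic_config(n_pairs = 60, seed = 8))
  imp <- feature_importance(syn$data, "extra_trees", seed = 1,
                            method = "impurity")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$rank, seq_len(nrow(imp)))
  expect_error(
    feature_importance(syn$data, "svr", seed = 1, method = "impurity"),
    "tree-based")
})

test_that("permutation importance highlights the dominant feature", {
  d <- toy_dataset(n = 80, p = 5, noise = 0.05, seed = 3,
                   target_fun = function(X) 2 * X[, 2])
  imp <- feature_importance(d, "ridge", seed = 1, method = "permutation",
                            augment = FALSE, k = 5)
  expect_identical(imp$feature[1], "a_f2")
})

test_that("swapped-pair augmentation makes predictions antisymmetric", {
  syn <- generate_synthetic_dataset(
    synthetic_config(n_pairs = 60, noise_sd = 0, seed = 13))
  d <- syn$data
  feats <- pair_feature_names(d)
  train <- dplyr::bind_rows(d, swap_pair_rows(d))
  fit <- fit_model("ridge", train[, feats], train$target, seed = 1)
  p_fwd <- predict(fit, d[, feats])
  p_rev <- predict(fit, swap_pair_rows(d)[, feats])
  expect_equal(p_rev, -p_fwd, tolerance = 1e-6)

  fit_et <- fit_model("extra_trees", train[, feats], train$target, seed = 1)
  asym <- predict(fit_et, d[, feats]) +
    predict(fit_et, swap_pair_rows(d)[, feats])
  expect_lt(mean(abs(asym)), 0.25 * stats::sd(d$target))
})

test_that("grouped evaluation and OOS keep held-out arenes out of training", {
  syn <- generate_synthetic_dataset(synthetic_config(n_arenes = 10, seed = 4))
  d <- syn$data
  grouped <- loo_evaluate(d, "ridge", seed = 1, mode = "arene")
  expect_equal(grouped$n, nrow(d))

  hold <- unique(d$arene_id)[1:2]
  oos <- oos_evaluate(d, hold, "ridge", seed = 1)
  expect_setequal(unique(oos$predictions$arene_id), hold)
  expect_equal(sort(c(oos$predictions$row,
                      which(!d$arene_id %in% hold))), seq_len(nrow(d)))
  expect_error(oos_evaluate(d, unique(d$arene_id), "ridge"), "every arene")
})

test_that("tidiers and plots expose report contents", {
  syn <- generate_synthetic_dataset(synthetic_config(n_arenes = 8, seed = 6))
  rep_ <- loo_evaluate(syn$data, "ridge", seed = 1)
  td <- tidy(rep_)
  expect_true(all(c("observed", "predicted", "residual") %in% names(td)))
  gl <- glance(rep_)
  expect_equal(gl$n_pairs, nrow(syn$data))
  expect_s3_class(autoplot(rep_), "ggplot")
  cmp <- compare_algorithms(syn$data, c("ridge", "linear"), seed = 1)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("model archives round-trip and reject schema tampering", {
  d <- toy_dataset(n = 20, p = 3)
  fit <- fit_model("ridge", d[, paste0("a_f", 1:3)], d$target, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(predict(back, d), predict(fit, d))
  archive <- readRDS(path)
  archive$model$features <- c("a_f1", "a_f2", "intruder")
  saveRDS(archive, path)
  expect_error(load_model(path), "schema hash mismatch")
})
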