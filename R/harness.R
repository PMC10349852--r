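.PAIR_META <- c("arene_id", "pair_id", "site_a", "site_b",
                "multiplicity_a", "multiplicity_b", "target")

#' Feature columns of a pair dataset
#'
#' A pair dataset is a tibble with one row per competing-site pair: metadata
#' columns (`arene_id`, `site_a`, `site_b`, `multiplicity_a`,
#' `multiplicity_b`, optionally `pair_id`), a numeric `target` (kcal/mol),
#' and numeric feature columns. Every column that is numeric and not
#' metadata is treated as a feature.
#'
#' @param data A pair-dataset tibble.
#' @return Character vector of feature column names.
#' @export
pair_feature_names <- function(data) {
  cand <- setdiff(names(data), .PAIR_META)
  cand[vapply(data[cand], is.numeric, logical(1))]
}

.check_pair_dataset <- function(data, features) {
  stopifnot(is.data.frame(data))
  if (!"arene_id" %in% names(data)) stop("pair dataset needs an `arene_id` column")
  if (!"target" %in% names(data)) stop("pair dataset needs a `target` column")
  if (anyNA(data$target)) stop("pair dataset has missing targets")
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) stop("missing feature column(s): ",
                             paste(miss, collapse = ", "))
  X <- as.matrix(data[, features, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values in pair dataset")
  invisible(TRUE)
}

#' Swap the site blocks of pair rows
#'
#' Returns the dataset with every `a_*` feature exchanged with its `b_*`
#' counterpart, `site_a`/`site_b` (and multiplicities) exchanged, and the
#' target negated. Under the delta encoding, `d_*` features are negated
#' instead. Used for swapped-pair training augmentation, which makes the
#' learned pairwise relation antisymmetric.
#'
#' @param data A pair-dataset tibble (blocks or delta encoding).
#' @return The swapped tibble, same shape as the input.
#' @export
swap_pair_rows <- function(data) {
  out <- data
  nm <- names(data)
  a_cols <- nm[startsWith(nm, "a_")]
  b_match <- sub("^a_", "b_", a_cols)
  if (length(a_cols) > 0 && all(b_match %in% nm)) {
    out[a_cols] <- data[b_match]
    out[b_match] <- data[a_cols]
  }
  d_cols <- nm[startsWith(nm, "d_")]
  for (dc in d_cols) out[[dc]] <- -data[[dc]]
  if (all(c("site_a", "site_b") %in% nm)) {
    out$site_a <- data$site_b
    out$site_b <- data$site_a
  }
  if (all(c("multiplicity_a", "multiplicity_b") %in% nm)) {
    out$multiplicity_a <- data$multiplicity_b
    out$multiplicity_b <- data$multiplicity_a
  }
  if ("target" %in% nm) out$target <- -data$target
  out
}

.metrics <- function(observed, predicted) {
  mae <- mean(abs(observed - predicted))
  r <- if (length(observed) < 2 || stats::sd(observed) == 0 ||
           stats::sd(predicted) == 0) {
    NaN
  } else {
    stats::cor(observed, predicted)
  }
  list(pearson_r = r, mae = mae)
}

.new_report <- function(algorithm, mode, predictions, features, seed,
                        extra = list()) {
  m <- .metrics(predictions$observed, predictions$predicted)
  structure(c(list(algorithm = algorithm, mode = mode,
                   pearson_r = m$pearson_r, mae = m$mae,
                   n = nrow(predictions), predictions = predictions,
                   features = features, seed = seed,
                   config_hash = rlang::hash(list(algorithm, mode, features,
                                                  seed, extra))),
              extra),
            class = "regiosel_report")
}

#' Leave-one-out evaluation of a registry algorithm
#'
#' For each fold the model is refit (fixed seed) on all remaining rows and
#' predicts the held-out rows; Pearson R and MAE are computed over the
#' concatenated held-out predictions (leave-one-out folds have size one, so
#' per-fold correlation is undefined). Two fold definitions are available:
#' `"pair"` (leave one pair out, the default) and `"arene"` (leave all pairs
#' of one arene out, so no training row shares an arene with the evaluated
#' rows).
#'
#' @param data A pair-dataset tibble (see [pair_feature_names()]).
#' @param algorithm Registry algorithm name.
#' @param seed Integer seed used for every fold's fit.
#' @param mode `"pair"` or `"arene"` fold unit.
#' @param features Feature subset to use (default: all feature columns).
#' @param augment Add swapped-pair rows to each training fold (default TRUE),
#'   enforcing antisymmetry by augmentation.
#' @return A `regiosel_report`: algorithm, mode, `pearson_r`, `mae`, held-out
#'   `predictions` tibble, feature list, seed and config hash. Constant
#'   targets yield `pearson_r = NaN` with a warning; MAE is still valid.
#' @export
loo_evaluate <- function(data, algorithm = "extra_trees", seed = 1,
                         mode = c("pair", "arene"), features = NULL,
                         augment = TRUE) {
  mode <- match.arg(mode)
  features <- features %||% pair_feature_names(data)
  .check_pair_dataset(data, features)
  if (nrow(data) < 3) stop("need at least 3 rows for leave-one-out evaluation")
  folds <- if (mode == "pair") {
    as.list(seq_len(nrow(data)))
  } else {
    unname(split(seq_len(nrow(data)), data$arene_id))
  }
  n <- nrow(data)
  aug <- if (augment) dplyr::bind_rows(data, swap_pair_rows(data)) else data
  Xall <- as.matrix(aug[, features, drop = FALSE])
  storage.mode(Xall) <- "double"
  yall <- aug$target
  arene_all <- aug$arene_id
  preds <- rep(NA_real_, n)
  for (fold in folds) {
    drop_idx <- if (augment) c(fold, fold + n) else fold
    if (mode == "arene") {
      stopifnot(!any(arene_all[-drop_idx] %in% data$arene_id[fold]))
    }
    fit <- fit_model(algorithm, Xall[-drop_idx, , drop = FALSE],
                     yall[-drop_idx], seed = seed)
    preds[fold] <- predict(fit, Xall[fold, , drop = FALSE])
  }
  predictions <- tibble::tibble(row = seq_len(nrow(data)),
                                arene_id = data$arene_id,
                                observed = data$target, predicted = preds)
  rep_ <- .new_report(algorithm, paste0("loo_", mode), predictions, features,
                      seed, extra = list(augment = augment))
  if (is.nan(rep_$pearson_r)) {
    warning("Pearson R undefined (constant observed or predicted targets)")
  }
  rep_
}

#' Evaluate and rank all registry algorithms
#'
#' Runs [loo_evaluate()] for each algorithm and ranks by Pearson R
#' (descending), ties broken by lower MAE. Deterministic for a fixed seed.
#'
#' @inheritParams loo_evaluate
#' @param algorithms Registry names to evaluate (default: full registry).
#' @return An object of class `regiosel_comparison`: a list of
#'   `regiosel_report`s, ranked. `glance()` returns the ranking table.
#' @export
compare_algorithms <- function(data, algorithms = names(model_registry()),
                               seed = 1, mode = "pair", features = NULL,
                               augment = TRUE) {
  reports <- lapply(algorithms, function(alg) {
    loo_evaluate(data, alg, seed = seed, mode = mode, features = features,
                 augment = augment)
  })
  key <- order(-vapply(reports, function(r) {
    ifelse(is.nan(r$pearson_r), -Inf, r$pearson_r)
  }, numeric(1)), vapply(reports, `[[`, numeric(1), "mae"))
  structure(reports[key], class = "regiosel_comparison")
}

#' Greedy forward feature selection
#'
#' Starts from the empty set and at each step adds the feature that
#' maximizes leave-one-out Pearson R (ties broken by lexicographic feature
#' name), stopping when no candidate improves R by more than `tolerance`.
#' The trajectory R is non-decreasing by construction.
#'
#' @inheritParams loo_evaluate
#' @param tolerance Minimal R improvement to accept another feature.
#' @param max_features Optional cap on the subset size.
#' @return A list with `features` (selected subset, in selection order),
#'   `trajectory` (tibble: step, feature, pearson_r, mae) and `report`
#'   (final `regiosel_report`).
#' @export
greedy_feature_selection <- function(data, algorithm = "extra_trees",
                                     seed = 1, mode = "pair",
                                     tolerance = 1e-3, max_features = Inf,
                                     augment = TRUE) {
  all_feats <- pair_feature_names(data)
  if (length(all_feats) < 2) stop("need at least 2 features to select from")
  selected <- character()
  best_r <- -Inf
  traj <- list()
  repeat {
    candidates <- sort(setdiff(all_feats, selected))
    if (length(candidates) == 0 || length(selected) >= max_features) break
    step_best <- NULL
    for (f in candidates) {
      rep_ <- suppressWarnings(
        loo_evaluate(data, algorithm, seed = seed, mode = mode,
                     features = c(selected, f), augment = augment))
      r <- ifelse(is.nan(rep_$pearson_r), -Inf, rep_$pearson_r)
      if (is.null(step_best) || r > step_best$r + 1e-12) {
        step_best <- list(f = f, r = r, report = rep_)
      }
    }
    if (step_best$r <= best_r + tolerance &&
        length(selected) > 0) break
    if (!is.finite(step_best$r) && length(selected) == 0) {
      # degenerate data: keep the first candidate to return something valid
      step_best$r <- -Inf
    }
    selected <- c(selected, step_best$f)
    best_r <- step_best$r
    traj[[length(traj) + 1L]] <- tibble::tibble(
      step = length(selected), feature = step_best$f,
      pearson_r = step_best$report$pearson_r, mae = step_best$report$mae)
    final_report <- step_best$report
    if (length(selected) >= length(all_feats)) break
  }
  list(features = selected, trajectory = dplyr::bind_rows(traj),
       report = final_report)
}

#' Feature importance of a fitted algorithm
#'
#' `method = "impurity"` refits a tree ensemble with impurity (variance
#' reduction) importances, normalized to sum to 1; it errors for non-tree
#' models. `method = "permutation"` fits once on the full data and reports,
#' for each feature, the mean degradation of Pearson R over `k` random
#' permutations of that column (clamped at 0).
#'
#' @inheritParams loo_evaluate
#' @param method `"impurity"` or `"permutation"`.
#' @param k Number of shuffles per feature for the permutation method.
#' @return A tibble `feature`, `importance`, `rank`, sorted by decreasing
#'   importance (ties broken by feature name).
#' @export
feature_importance <- function(data, algorithm = "extra_trees", seed = 1,
                               method = c("impurity", "permutation"),
                               features = NULL, augment = TRUE, k = 10) {
  method <- match.arg(method)
  features <- features %||% pair_feature_names(data)
  .check_pair_dataset(data, features)
  reg <- model_registry()
  if (!algorithm %in% names(reg)) stop("unknown algorithm '", algorithm, "'")
  train <- if (augment) dplyr::bind_rows(data, swap_pair_rows(data)) else data
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train$target
  if (method == "impurity") {
    if (!reg[[algorithm]]$tree_based) {
      stop("impurity importances require a tree-based algorithm, not '",
           algorithm, "'")
    }
    if (algorithm %in% c("extra_trees", "random_forest")) {
      set.seed(seed)
      fit <- .fit_ranger(X, y, seed,
                         splitrule = if (algorithm == "extra_trees")
                           "extratrees" else "variance",
                         mtry = if (algorithm == "extra_trees") ncol(X) else
                           floor(ncol(X) / 3),
                         importance = "impurity")
      imp <- fit$variable.importance[features]
    } else {
      fit <- fit_model(algorithm, X, y, seed = seed)
      tbl <- xgboost::xgb.importance(model = fit$model)
      imp <- stats::setNames(rep(0, length(features)), features)
      imp[tbl$Feature] <- tbl$Gain
    }
    imp <- pmax(imp, 0)
    imp <- imp / sum(imp)
  } else {
    fit <- fit_model(algorithm, X, y, seed = seed)
    base_r <- stats::cor(y, predict(fit, X))
    set.seed(seed + 1L)
    imp <- vapply(features, function(f) {
      drops <- vapply(seq_len(k), function(i) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base_r - stats::cor(y, predict(fit, Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    imp <- pmax(imp, 0)
  }
  out <- tibble::tibble(feature = features, importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Out-of-sample evaluation with held-out arenes
#'
#' Removes every pair of the held-out arenes from the training set, fits on
#' the remainder, and evaluates on the held-out pairs only — mimicking
#' prospective prediction for unseen substrates.
#'
#' @inheritParams loo_evaluate
#' @param holdout_arene_ids Arene identifiers to withhold.
#' @return A `regiosel_report` over the held-out pairs. A holdout with zero
#'   pairs yields an empty report (`n = 0`) with a warning.
#' @export
oos_evaluate <- function(data, holdout_arene_ids, algorithm = "extra_trees",
                         seed = 1, features = NULL, augment = TRUE) {
  features <- features %||% pair_feature_names(data)
  .check_pair_dataset(data, features)
  miss <- setdiff(holdout_arene_ids, unique(data$arene_id))
  if (length(miss) > 0) {
    warning("holdout arene(s) contribute no pairs: ",
            paste(miss, collapse = ", "))
  }
  test_idx <- which(data$arene_id %in% holdout_arene_ids)
  train <- data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE]
  if (nrow(train) == 0) stop("holdout covers every arene; training set empty")
  stopifnot(length(intersect(train$arene_id, holdout_arene_ids)) == 0)
  if (length(test_idx) == 0) {
    warning("holdout contains no pairs; empty out-of-sample report")
    predictions <- tibble::tibble(row = integer(), arene_id = character(),
                                  observed = numeric(), predicted = numeric())
    return(.new_report(algorithm, "oos", predictions, features, seed,
                       extra = list(holdout = holdout_arene_ids)))
  }
  if (augment) train <- dplyr::bind_rows(train, swap_pair_rows(train))
  fit <- fit_model(algorithm, train[, features, drop = FALSE], train$target,
                   seed = seed)
  predictions <- tibble::tibble(
    row = test_idx, arene_id = data$arene_id[test_idx],
    observed = data$target[test_idx],
    predicted = predict(fit, data[test_idx, , drop = FALSE]))
  suppressWarnings(
    .new_report(algorithm, "oos", predictions, features, seed,
                extra = list(holdout = holdout_arene_ids)))
}
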