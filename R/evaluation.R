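# Dataset splitting, 5-fold cross-validation, grid search (including the
# minimum train-validation-gap criterion used to pick the ridge penalty),
# R^2, test-set trendline diagnostics, and the end-to-end pipeline.

#' Shuffled train/test split
#'
#' @param n number of rows.
#' @param fraction training fraction in (0, 1); train size is
#'   `floor(fraction * n)`.
#' @param seed shuffle seed.
#' @return list with integer `train` and `test` row indices (disjoint,
#'   exhaustive) plus the seed and fraction.
#' @export
split_dataset <- function(n, fraction = 0.8, seed = 1L) {
  if (n < 2) stop("need at least 2 rows to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  perm <- .with_seed(seed, sample.int(n))
  ntrain <- floor(fraction * n)
  list(train = sort(perm[seq_len(ntrain)]),
       test = sort(perm[(ntrain + 1):n]),
       fraction = fraction, seed = seed)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true observed values (non-constant, length >= 2).
#' @param y_pred predictions.
#' @return numeric scalar (can be negative for models worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("zero-variance reference values: R^2 undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Model specification for cross-validation and grid search
#'
#' Packs a model family and its parameters into a fit closure.
#'
#' @param family one of `"ridge"`, `"cart"`, `"random_forest"`,
#'   `"extra_trees"`, `"gradient_boosting"`.
#' @param ... family parameters passed to the fit function.
#' @return list with `family`, `params` and `fit(X, y)`.
#' @export
model_spec <- function(family = c("ridge", "cart", "random_forest",
                                  "extra_trees", "gradient_boosting"), ...) {
  family <- match.arg(family)
  params <- list(...)
  fit <- switch(family,
    ridge = function(X, y) do.call(fit_ridge, c(list(X, y), params)),
    cart = function(X, y) do.call(fit_cart, c(list(X, y), params)),
    random_forest = function(X, y)
      do.call(fit_forest, c(list(X, y, mode = "random_forest"), params)),
    extra_trees = function(X, y)
      do.call(fit_forest, c(list(X, y, mode = "extra_trees"), params)),
    gradient_boosting = function(X, y) do.call(fit_gbr, c(list(X, y), params)))
  list(family = family, params = params, fit = fit)
}

# seeded shuffled fold assignment, contiguous chunks, sizes differing <= 1
.fold_assignment <- function(n, folds, fold_seed) {
  perm <- .with_seed(fold_seed, sample.int(n))
  sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds),
                                       rep(0, folds - n %% folds))
  rep(seq_len(folds), sizes)[order(perm)]
}

#' K-fold cross-validation of a model specification
#'
#' Seeded shuffled fold assignment; per fold the model is fitted on the
#' remaining folds and R^2 is computed on both parts.  Fold-wise values are
#' averaged (not pooled).
#'
#' @param spec a [model_spec()].
#' @param X descriptor table.
#' @param y response.
#' @param folds number of folds (default 5).
#' @param fold_seed fold-assignment seed.
#' @return list with per-fold data.frame and `mean_train_r2`,
#'   `mean_val_r2`.
#' @export
cross_validate <- function(spec, X, y, folds = 5L, fold_seed = 1L) {
  X <- .as_matrix(X)
  n <- nrow(X)
  if (n < folds) stop("fewer rows than folds")
  fa <- .fold_assignment(n, folds, fold_seed)
  per <- lapply(seq_len(folds), function(f) {
    tr <- which(fa != f); va <- which(fa == f)
    fit <- spec$fit(X[tr, , drop = FALSE], y[tr])
    c(train_r2 = r_squared(y[tr], predict(fit, X[tr, , drop = FALSE])),
      val_r2 = r_squared(y[va], predict(fit, X[va, , drop = FALSE])))
  })
  per <- do.call(rbind, per)
  list(folds = as.data.frame(per),
       mean_train_r2 = mean(per[, "train_r2"]),
       mean_val_r2 = mean(per[, "val_r2"]),
       fold_seed = fold_seed)
}

#' Exhaustive grid search over model hyperparameters
#'
#' Evaluates every grid point by cross-validation and selects by either the
#' maximum mean validation R^2 or the minimum train-validation gap.  Ties
#' are broken toward stronger regularization / smaller models (larger
#' `lambda`, smaller `max_depth`, fewer `n_estimators`, smaller
#' `learning_rate`).
#'
#' @param family model family (see [model_spec()]).
#' @param grid named list of parameter vectors (crossed).
#' @param X,y data.
#' @param criterion `"max_val_r2"` (default) or `"min_train_val_gap"`.
#' @param folds,fold_seed CV controls.
#' @param ... fixed parameters passed to every fit.
#' @return list with `results` data.frame (one row per grid point, with
#'   mean train/validation R^2), `best` (selected parameter list) and
#'   `criterion`.
#' @export
grid_search <- function(family, grid, X, y,
                        criterion = c("max_val_r2", "min_train_val_gap"),
                        folds = 5L, fold_seed = 1L, ...) {
  criterion <- match.arg(criterion)
  if (!length(grid)) stop("empty grid")
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fixed <- list(...)
  res <- lapply(seq_len(nrow(pts)), function(r) {
    params <- c(as.list(pts[r, , drop = FALSE]), fixed)
    spec <- do.call(model_spec, c(list(family = family), params))
    cv <- cross_validate(spec, X, y, folds = folds, fold_seed = fold_seed)
    data.frame(pts[r, , drop = FALSE],
               mean_train_r2 = cv$mean_train_r2,
               mean_val_r2 = cv$mean_val_r2)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$gap <- res$mean_train_r2 - res$mean_val_r2
  score <- if (criterion == "max_val_r2") res$mean_val_r2 else -res$gap
  # preference order for ties: stronger regularization / smaller model first
  pref <- rep(0, nrow(res))
  if ("lambda" %in% names(res)) pref <- pref - res$lambda
  if ("max_depth" %in% names(res)) pref <- pref + res$max_depth
  if ("n_estimators" %in% names(res)) pref <- pref + res$n_estimators / 1e3
  if ("learning_rate" %in% names(res)) pref <- pref + res$learning_rate
  ord <- order(-score, pref)
  best_row <- ord[1]
  list(results = res, best = as.list(pts[best_row, , drop = FALSE]),
       best_index = best_row, criterion = criterion)
}

#' Test-set trendline diagnostics
#'
#' Least-squares line of the reference values on the model predictions
#' (the `(E_model, E_reference)` orientation), with the R^2 of that fit.
#' A perfect model gives slope 1, intercept 0, R^2 1.
#'
#' @param y_model model predictions.
#' @param y_reference reference values.
#' @param reverse regress predictions on reference instead.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
trendline <- function(y_model, y_reference, reverse = FALSE) {
  if (length(y_model) != length(y_reference)) stop("length mismatch")
  if (length(y_model) < 3) stop("need at least 3 points for a trendline")
  x <- if (reverse) y_reference else y_model
  yy <- if (reverse) y_model else y_reference
  if (sd_pop(x) == 0) stop("zero-variance predictions: trendline undefined")
  fit <- stats::lm(yy ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r_squared(yy, stats::fitted(fit)))
}

#' Default model configurations of the comparison
#'
#' The five families with the hyperparameters selected by the grid-search
#' protocol: ridge `lambda = 0.1` (minimum train-validation gap), trees of
#' depth 3, 10-tree random forest, 15-tree extra trees, gradient boosting
#' with 50 stages at learning rate 0.05.
#'
#' @param seed seed forwarded to the stochastic ensembles.
#' @return named list of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  list(
    ridge = model_spec("ridge", lambda = 0.1),
    cart = model_spec("cart", max_depth = 3L),
    random_forest = model_spec("random_forest", n_estimators = 10L,
                               max_depth = 3L, seed = seed),
    extra_trees = model_spec("extra_trees", n_estimators = 15L,
                             max_depth = 3L, seed = seed),
    gradient_boosting = model_spec("gradient_boosting", n_estimators = 50L,
                                   learning_rate = 0.05, max_depth = 3L,
                                   seed = seed)
  )
}

#' Run the end-to-end screening pipeline
#'
#' Generates (or accepts) a dataset, splits it 80/20, performs descriptor
#' selection on the training rows only, cross-validates the five model
#' families on the training rows, fits them on the full training set, and
#' evaluates predictions and trendlines on the held-out test set.  Test-row
#' labels are never visible to selection or tuning.
#'
#' @param config list: `seed` (default 1), `dataset` (a
#'   [generate_dataset()] result; generated from the seed when missing),
#'   `train_fraction` (0.8), `selection` (config list for
#'   [select_descriptors()]), `grid_search` (logical, default `FALSE`: use
#'   the default hyperparameters), `out_dir` (optional; JSON/CSV reports
#'   are written there).
#' @return list with `split`, `selection`, `cv` (per family), `test`
#'   (per-family R^2 and trendline), `importances`, `predictions`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(seed = 1L, train_fraction = 0.8,
                                selection = list(), grid_search = FALSE,
                                allow_test_leakage = FALSE), config)
  if (isTRUE(cfg$allow_test_leakage)) {
    stop("refusing to run with test-set leakage enabled: descriptor ",
         "selection and tuning must only ever see training rows")
  }
  ds <- cfg$dataset
  if (is.null(ds)) ds <- generate_dataset(synthetic_spec(seed = cfg$seed))
  X <- .as_matrix(ds$features[, setdiff(colnames(ds$features), "canonical")])
  y <- ds$labels$delta_E_V
  n <- nrow(X)

  sp <- split_dataset(n, fraction = cfg$train_fraction, seed = cfg$seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]

  sel_cfg <- utils::modifyList(list(fold_seed = cfg$seed + 1L), cfg$selection)
  sel <- select_descriptors(Xtr, ytr, sel_cfg)
  Xtr_s <- Xtr[, sel$survivors, drop = FALSE]
  Xte_s <- Xte[, sel$survivors, drop = FALSE]

  specs <- default_model_specs(seed = cfg$seed + 2L)
  if (isTRUE(cfg$grid_search)) {
    gs <- list(
      ridge = grid_search("ridge", list(lambda = c(0.001, 0.01, 0.1, 1, 10, 100)),
                          Xtr_s, ytr, criterion = "min_train_val_gap",
                          fold_seed = cfg$seed + 1L),
      cart = grid_search("cart", list(max_depth = 2:20), Xtr_s, ytr,
                         fold_seed = cfg$seed + 1L),
      random_forest = grid_search("random_forest",
                                  list(n_estimators = c(5L, 10L, 15L, 20L)),
                                  Xtr_s, ytr, max_depth = 3L,
                                  seed = cfg$seed + 2L,
                                  fold_seed = cfg$seed + 1L),
      extra_trees = grid_search("extra_trees",
                                list(n_estimators = c(5L, 10L, 15L, 20L)),
                                Xtr_s, ytr, max_depth = 3L,
                                seed = cfg$seed + 2L,
                                fold_seed = cfg$seed + 1L),
      gradient_boosting = grid_search("gradient_boosting",
                                      list(learning_rate = c(0.05, 0.1, 0.5),
                                           n_estimators = c(25L, 50L)),
                                      Xtr_s, ytr, max_depth = 3L,
                                      fold_seed = cfg$seed + 1L))
    specs <- lapply(names(gs), function(f) {
      do.call(model_spec, c(list(family = f), gs[[f]]$best,
                            if (f %in% c("random_forest", "extra_trees"))
                              list(max_depth = 3L, seed = cfg$seed + 2L)
                            else if (f == "gradient_boosting")
                              list(max_depth = 3L) else NULL))
    })
    names(specs) <- names(gs)
  } else {
    gs <- NULL
  }

  cv <- lapply(specs, function(s) {
    cross_validate(s, Xtr_s, ytr, fold_seed = cfg$seed + 1L)
  })
  fits <- lapply(specs, function(s) s$fit(Xtr_s, ytr))
  test <- lapply(fits, function(fit) {
    pred <- predict(fit, Xte_s)
    list(r2 = r_squared(yte, pred), trendline = trendline(pred, yte),
         predictions = pred)
  })
  importances <- lapply(fits[c("cart", "random_forest", "extra_trees",
                               "gradient_boosting")], feature_importances)

  predictions <- data.frame(canonical = ds$labels$canonical[sp$test],
                            E_reference = yte)
  for (f in names(test)) predictions[[paste0("E_", f)]] <- test[[f]]$predictions

  report <- list(seed = cfg$seed, split = sp, selection = sel,
                 grid_search = gs,
                 cv = lapply(cv, function(z)
                   z[c("mean_train_r2", "mean_val_r2", "fold_seed")]),
                 test = lapply(test, function(z) z[c("r2", "trendline")]),
                 importances = importances,
                 predictions = predictions,
                 fits = fits)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(predictions,
                     file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    slim <- report[c("seed", "cv", "test", "importances")]
    slim$selection <- list(survivors = sel$survivors,
                           stage_counts = as.list(sel$stage_counts))
    jsonlite::write_json(slim, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
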