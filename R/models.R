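# The five regressors, implemented from their defining equations: ridge
# closed form, CART with exhaustive split search, random forest, extra
# trees, and gradient boosting on residuals.

# ---------------------------------------------------------------- ridge ----

#' Fit a ridge regression model (closed form)
#'
#' Solves `beta = (X'X + lambda I)^-1 X' y` with a leading ones column, the
#' penalty applied to all `m + 1` coefficients including the intercept (a
#' conventional unpenalized-intercept mode is available).  At `lambda = 0`
#' a singular system falls back to the Moore-Penrose pseudo-inverse.
#'
#' @param X numeric matrix or data.frame of descriptors (no intercept
#'   column).
#' @param y numeric response.
#' @param lambda non-negative regularization coefficient.
#' @param penalize_intercept include the intercept in the penalty
#'   (default `TRUE`, matching the closed form above).
#' @param standardize center/scale columns before fitting (off by default);
#'   parameters are stored in the model and applied at prediction.
#' @return object of class `ridge_model`.
#' @export
fit_ridge <- function(X, y, lambda = 0, penalize_intercept = TRUE,
                      standardize = FALSE) {
  X <- .as_matrix(X)
  if (lambda < 0) stop("lambda must be non-negative")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  std <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sc <- apply(X, 2, sd_pop)
    sc[sc == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sc, "/")
    std <- list(center = mu, scale = sc)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  P <- diag(p)
  if (!penalize_intercept) P[1, 1] <- 0
  A <- crossprod(Xd) + lambda * P
  b <- crossprod(Xd, y)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) {
    if (lambda > 0) stop("ridge system unexpectedly singular")
    beta <- .pinv_solve(Xd, y)
  }
  beta <- drop(beta)
  if (any(!is.finite(beta))) stop("non-finite ridge coefficients")
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 lambda = lambda, columns = colnames(X),
                 penalize_intercept = penalize_intercept,
                 standardize = std),
            class = "ridge_model")
}

# Minimum-norm least squares via SVD (used when X'X is singular at
# lambda = 0); reports the collinear columns in the error path of callers.
.pinv_solve <- function(Xd, y, tol = 1e-10) {
  sv <- svd(Xd)
  d <- sv$d
  pos <- d > tol * max(d)
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / d[pos]))
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- .check_columns(newdata, object$columns)
  if (!is.null(object$standardize)) {
    X <- sweep(sweep(X, 2, object$standardize$center), 2,
               object$standardize$scale, "/")
  }
  drop(cbind(1, X) %*% object$coefficients)
}

.check_columns <- function(newdata, columns) {
  X <- .as_matrix(newdata)
  if (!all(columns %in% colnames(X))) {
    stop("prediction data is missing column(s): ",
         paste(setdiff(columns, colnames(X)), collapse = ", "))
  }
  X[, columns, drop = FALSE]
}

# ----------------------------------------------------------------- CART ----

# Node cost H(Q): mean squared error around the node mean, or the mean
# Poisson half-deviance 2/n sum(y log(y/ybar) - y + ybar) (requires y > 0).
.node_cost <- function(y, cost) {
  m <- mean(y)
  if (cost == "mse") return(mean((y - m)^2))
  2 * mean(y * log(y / m) - y + m)
}

# Exhaustive best split of one feature: thresholds at midpoints of
# consecutive sorted unique values; returns the weighted child cost
# n_l H_l + n_r H_r minimized over thresholds (vectorized via cumsums).
.best_split_feature <- function(x, y, min_leaf, cost) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cut_ok <- which(diff(xs) > 0)                   # split after position k
  cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
  if (!length(cut_ok)) return(NULL)
  if (cost == "mse") {
    cy <- cumsum(ys); cy2 <- cumsum(ys^2)
    k <- cut_ok
    sl <- cy[k]; sl2 <- cy2[k]
    sr <- cy[n] - sl; sr2 <- cy2[n] - sl2
    child <- (sl2 - sl^2 / k) + (sr2 - sr^2 / (n - k))   # n_l H_l + n_r H_r
  } else {
    cy <- cumsum(ys); cyl <- cumsum(ys * log(ys))
    k <- cut_ok
    sl <- cy[k]; sll <- cyl[k]
    sr <- cy[n] - sl; srl <- cyl[n] - sll
    child <- 2 * ((sll - sl * log(sl / k) - sl + sl) +
                  (srl - sr * log(sr / (n - k)) - sr + sr))
    # the -y + ybar terms cancel in the sums: sum(ybar) = sum(y) per child
  }
  b <- which.min(child)
  k <- cut_ok[b]
  list(threshold = (xs[k] + xs[k + 1]) / 2, child_cost = child[b])
}

# Recursive tree growth.  feature_sampler(m) returns candidate feature
# indices per node; threshold_mode "exhaustive" (CART/RF) or "random"
# (extra trees, one uniform threshold per candidate feature).
.grow_tree <- function(X, y, depth, max_depth, min_leaf, cost,
                       feature_sampler, threshold_mode) {
  n <- length(y)
  H <- .node_cost(y, cost)
  leaf <- list(leaf = TRUE, value = mean(y), n = n, cost = H)
  if (depth >= max_depth || n < 2 * min_leaf || H <= 1e-14) return(leaf)
  feats <- feature_sampler(ncol(X))
  best <- NULL
  for (j in feats) {
    x <- X[, j]
    if (threshold_mode == "exhaustive") {
      sp <- .best_split_feature(x, y, min_leaf, cost)
      if (is.null(sp)) next
      t <- sp$threshold; child <- sp$child_cost
    } else {
      lo <- min(x); hi <- max(x)
      if (lo == hi) next
      t <- stats::runif(1, lo, hi)
      left <- x < t
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      child <- nl * .node_cost(y[left], cost) +
        (n - nl) * .node_cost(y[!left], cost)
    }
    dec <- n * H - child
    # strict improvement keeps the first-encountered best (feature order,
    # then ascending threshold within .best_split_feature)
    if (is.null(best) || dec > best$decrease + 1e-12) {
      best <- list(feature = j, threshold = t, decrease = dec)
    }
  }
  if (is.null(best) || best$decrease <= 1e-12) return(leaf)
  left <- X[, best$feature] < best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n = n, cost = H, decrease = best$decrease,
       left = .grow_tree(X[left, , drop = FALSE], y[left], depth + 1,
                         max_depth, min_leaf, cost, feature_sampler,
                         threshold_mode),
       right = .grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1,
                          max_depth, min_leaf, cost, feature_sampler,
                          threshold_mode))
}

#' Fit a CART regression tree
#'
#' Greedy recursive binary splitting: at each node every feature and every
#' candidate threshold (midpoints of consecutive sorted unique values) is
#' examined and the split with the largest decrease of
#' `n H(Q) - n_l H(Q_l) - n_r H(Q_r)` is kept; rows with `x_j < t` go left.
#' Leaves predict their training mean.  Ties are broken deterministically
#' (first feature in column order, lowest threshold).
#'
#' @param X descriptor matrix/data.frame.
#' @param y numeric response.
#' @param max_depth maximum depth (0 = single leaf).
#' @param min_samples_leaf minimum rows per leaf (default 1).
#' @param cost `"mse"` (default) or `"poisson"` (requires `y > 0`).
#' @return object of class `cart_model`.
#' @export
fit_cart <- function(X, y, max_depth = 3L, min_samples_leaf = 1L,
                     cost = c("mse", "poisson")) {
  X <- .as_matrix(X)
  cost <- match.arg(cost)
  if (!length(y) || nrow(X) != length(y)) stop("empty or mismatched data")
  if (cost == "poisson" && any(y <= 0)) {
    stop("poisson cost requires strictly positive targets")
  }
  root <- .grow_tree(X, y, 0L, max_depth, min_samples_leaf, cost,
                     feature_sampler = function(m) seq_len(m),
                     threshold_mode = "exhaustive")
  structure(list(root = root, columns = colnames(X),
                 params = list(max_depth = max_depth,
                               min_samples_leaf = min_samples_leaf,
                               cost = cost)),
            class = "cart_model")
}

.predict_node <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$value; return(out) }
  left <- X[idx, node$feature] < node$threshold
  out <- .predict_node(node$left, X, idx[left], out)
  .predict_node(node$right, X, idx[!left], out)
}

#' @export
predict.cart_model <- function(object, newdata, ...) {
  X <- .check_columns(newdata, object$columns)
  .predict_node(object$root, X, seq_len(nrow(X)), numeric(nrow(X)))
}

#' Indented textual rendering of a fitted tree
#'
#' @param model a `cart_model` (or a single member of an ensemble).
#' @return character vector, one line per node.
#' @export
tree_export <- function(model) {
  cols <- model$columns
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      return(sprintf("%sleaf: value=%.4f n=%d cost=%.5f",
                     pad, node$value, node$n, node$cost))
    }
    c(sprintf("%sif %s < %.4f  (n=%d, cost decrease=%.5f)",
              pad, cols[node$feature], node$threshold, node$n, node$decrease),
      walk(node$left, indent + 1),
      sprintf("%selse (%s >= %.4f)", pad, cols[node$feature], node$threshold),
      walk(node$right, indent + 1))
  }
  walk(model$root, 0)
}

# ------------------------------------------------------------ ensembles ----

#' Fit a random forest or extra trees ensemble
#'
#' Random forest: each tree is grown on a bootstrap sample (with
#' replacement, size n) with a random feature subset per split
#' (`ceiling(m/3)` by default) and exhaustive threshold search.  Extra
#' trees: each tree is grown on a subsample without replacement (fraction
#' `subsample`), with a random feature subset per split and one uniformly
#' random threshold per candidate feature.  Prediction is the mean over
#' member trees.
#'
#' @param X descriptor matrix/data.frame.
#' @param y response.
#' @param mode `"random_forest"` or `"extra_trees"`.
#' @param n_estimators number of trees.
#' @param max_depth per-tree depth limit.
#' @param min_samples_leaf minimum rows per leaf.
#' @param mtry features per split (default `ceiling(m/3)`).
#' @param bootstrap random forest only: draw bootstrap samples
#'   (default `TRUE`).
#' @param subsample extra trees only: subsample fraction in (0, 1]
#'   (default 0.8; 1 means no subsampling).
#' @param seed RNG seed; fits are reproducible from (data, params, seed).
#' @return object of class `ensemble_model`.
#' @export
fit_forest <- function(X, y, mode = c("random_forest", "extra_trees"),
                       n_estimators = 10L, max_depth = 3L,
                       min_samples_leaf = 1L, mtry = NULL,
                       bootstrap = TRUE, subsample = 0.8, seed = 1L) {
  X <- .as_matrix(X)
  mode <- match.arg(mode)
  if (n_estimators < 1) stop("n_estimators must be >= 1")
  if (mode == "extra_trees" && (subsample <= 0 || subsample > 1)) {
    stop("subsample fraction must be in (0, 1]")
  }
  n <- nrow(X); m <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(m / 3)
  mtry <- min(m, max(1L, as.integer(mtry)))
  trees <- .with_seed(seed, lapply(seq_len(n_estimators), function(t) {
    rows <- if (mode == "random_forest") {
      if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    } else {
      sample.int(n, max(2L, floor(subsample * n)), replace = FALSE)
    }
    sampler <- if (mtry >= m) function(mm) seq_len(mm)
    else function(mm) sort(sample.int(mm, mtry))
    .grow_tree(X[rows, , drop = FALSE], y[rows], 0L, max_depth,
               min_samples_leaf, "mse", sampler,
               if (mode == "extra_trees") "random" else "exhaustive")
  }))
  structure(list(trees = trees, mode = mode, columns = colnames(X),
                 params = list(n_estimators = n_estimators,
                               max_depth = max_depth,
                               min_samples_leaf = min_samples_leaf,
                               mtry = mtry, bootstrap = bootstrap,
                               subsample = subsample, seed = seed)),
            class = "ensemble_model")
}

#' Fit gradient boosting regression
#'
#' `F_0 = mean(y)`; each stage fits a CART tree (MSE cost) to the current
#' residuals `y - F_{m-1}(x)` and the model is updated as
#' `F_m = F_{m-1} + gamma h_m`.
#'
#' @param X descriptor matrix/data.frame.
#' @param y response.
#' @param n_estimators number of boosting stages M (0 gives the constant
#'   mean model).
#' @param learning_rate shrinkage gamma in (0, 1].
#' @param max_depth per-tree depth.
#' @param min_samples_leaf minimum rows per leaf.
#' @param seed RNG seed (kept for interface symmetry; the fit is
#'   deterministic).
#' @return object of class `ensemble_model` with `mode = "gradient_boosting"`.
#' @export
fit_gbr <- function(X, y, n_estimators = 50L, learning_rate = 0.05,
                    max_depth = 3L, min_samples_leaf = 1L, seed = 1L) {
  X <- .as_matrix(X)
  if (n_estimators < 0) stop("n_estimators must be >= 0")
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1]")
  }
  f0 <- mean(y)
  fx <- rep(f0, length(y))
  trees <- vector("list", n_estimators)
  for (t in seq_len(n_estimators)) {
    res <- y - fx
    tr <- .grow_tree(X, res, 0L, max_depth, min_samples_leaf, "mse",
                     function(m) seq_len(m), "exhaustive")
    trees[[t]] <- tr
    fx <- fx + learning_rate *
      .predict_node(tr, X, seq_len(nrow(X)), numeric(nrow(X)))
  }
  structure(list(trees = trees, mode = "gradient_boosting",
                 columns = colnames(X), f0 = f0,
                 params = list(n_estimators = n_estimators,
                               learning_rate = learning_rate,
                               max_depth = max_depth,
                               min_samples_leaf = min_samples_leaf,
                               seed = seed)),
            class = "ensemble_model")
}

#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  X <- .check_columns(newdata, object$columns)
  n <- nrow(X)
  if (object$mode == "gradient_boosting") {
    out <- rep(object$f0, n)
    for (tr in object$trees) {
      out <- out + object$params$learning_rate *
        .predict_node(tr, X, seq_len(n), numeric(n))
    }
    return(out)
  }
  preds <- vapply(object$trees, function(tr) {
    .predict_node(tr, X, seq_len(n), numeric(n))
  }, numeric(n))
  if (n == 1L) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# run expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ------------------------------------------------------------ importance ----

#' Split-based feature importances
#'
#' Per-feature total cost decrease `n H - n_l H_l - n_r H_r` accumulated
#' over splits and normalized to sum one; for ensembles, member importances
#' are averaged and renormalized.
#'
#' @param model a `cart_model` or `ensemble_model`.
#' @return named numeric vector over the training columns.
#' @export
feature_importances <- function(model) {
  cols <- model$columns
  one_tree <- function(root) {
    imp <- stats::setNames(numeric(length(cols)), cols)
    walk <- function(node) {
      if (node$leaf) return(invisible(NULL))
      imp[node$feature] <<- imp[node$feature] + node$decrease
      walk(node$left); walk(node$right)
    }
    walk(root)
    imp
  }
  if (inherits(model, "cart_model")) {
    imp <- one_tree(model$root)
  } else {
    mats <- lapply(model$trees, one_tree)
    mats <- lapply(mats, function(v) if (sum(v) > 0) v / sum(v) else v)
    imp <- Reduce(`+`, mats) / length(mats)
  }
  s <- sum(imp)
  if (s == 0) {
    warning("model contains no splits; importances are all zero")
    return(imp)
  }
  imp / s
}

# ---------------------------------------------------------- serialization ----

.serialize_node <- function(node) {
  if (node$leaf) {
    list(leaf = TRUE, value = node$value, n = node$n, cost = node$cost)
  } else {
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         n = node$n, cost = node$cost, decrease = node$decrease,
         left = .serialize_node(node$left), right = .serialize_node(node$right))
  }
}

.deserialize_node <- function(x) {
  if (isTRUE(x$leaf)) {
    list(leaf = TRUE, value = x$value, n = as.integer(x$n), cost = x$cost)
  } else {
    list(leaf = FALSE, feature = as.integer(x$feature),
         threshold = x$threshold, n = as.integer(x$n), cost = x$cost,
         decrease = x$decrease, left = .deserialize_node(x$left),
         right = .deserialize_node(x$right))
  }
}

#' Serialize a fitted model to JSON
#'
#' Round-trip load -> predict is bit-identical (full-precision numbers).
#'
#' @param model a `ridge_model`, `cart_model` or `ensemble_model`.
#' @param path output file.
#' @export
model_to_json <- function(model, path) {
  obj <- if (inherits(model, "ridge_model")) {
    list(type = "ridge", coefficients = as.list(model$coefficients),
         lambda = model$lambda, columns = model$columns,
         penalize_intercept = model$penalize_intercept,
         standardize = model$standardize)
  } else if (inherits(model, "cart_model")) {
    list(type = "cart", root = .serialize_node(model$root),
         columns = model$columns, params = model$params)
  } else {
    list(type = "ensemble", mode = model$mode,
         trees = lapply(model$trees, .serialize_node),
         columns = model$columns, params = model$params,
         f0 = model$f0)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
}

#' Load a model serialized by [model_to_json()]
#' @param path JSON file.
#' @return the fitted model object.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (x$type == "ridge") {
    structure(list(
      coefficients = stats::setNames(unlist(x$coefficients),
                                     names(x$coefficients)),
      lambda = x$lambda, columns = unlist(x$columns),
      penalize_intercept = isTRUE(x$penalize_intercept),
      standardize = if (is.null(x$standardize)) NULL else
        list(center = unlist(x$standardize$center),
             scale = unlist(x$standardize$scale))),
      class = "ridge_model")
  } else if (x$type == "cart") {
    structure(list(root = .deserialize_node(x$root),
                   columns = unlist(x$columns),
                   params = x$params), class = "cart_model")
  } else {
    structure(list(trees = lapply(x$trees, .deserialize_node),
                   mode = x$mode, columns = unlist(x$columns),
                   params = x$params, f0 = x$f0),
              class = "ensemble_model")
  }
}
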