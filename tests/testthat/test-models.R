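test_that("ridge closed form matches hand-solved cases", {
  X <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, 2, 3)
  b0 <- fit_ridge(X, y, lambda = 0)
  expect_equal(unname(b0$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(predict(b0, X), y, tolerance = 1e-10)
  # lambda = 1: solve [[4, 6], [6, 15]] beta = [6, 14]
  b1 <- fit_ridge(X, y, lambda = 1)
  expect_equal(unname(b1$coefficients), c(0.25, 5 / 6), tolerance = 1e-10)
  # extreme shrinkage drives all coefficients to zero
  bb <- fit_ridge(X, y, lambda = 1e6)
  expect_lt(sqrt(sum(bb$coefficients^2)), 1e-3)
})

test_that("ridge equals the normal-equation oracle on random instances", {
  set.seed(101)
  for (t in 1:50) {
    m <- sample(1:10, 1); n <- sample((m + 3):40, 1)
    X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("x", 1:m)))
    y <- rnorm(n)
    lambda <- sample(c(0, 0.1, 1, 10), 1)
    got <- fit_ridge(X, y, lambda = lambda)$coefficients
    want <- ridge_oracle(X, y, lambda)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("ridge coefficient norm is non-increasing in lambda", {
  set.seed(5)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(30, 0, 0.3)
  norms <- vapply(10^seq(-3, 6), function(l) {
    sqrt(sum(fit_ridge(X, y[, 1], lambda = l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("singular designs at lambda 0 fall back to the pseudo-inverse", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))   # perfectly collinear
  y <- c(2, 4, 6, 8)
  fit <- fit_ridge(X, y, lambda = 0)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("CART reproduces hand-worked splits and degenerate cases", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(0, 0, 10, 10)
  tr <- fit_cart(X, y, max_depth = 1)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$threshold, 2.5)
  expect_equal(predict(tr, X), y)                     # training MSE 0
  # constant targets: a single leaf at any depth
  trc <- fit_cart(X, rep(5, 4), max_depth = 10)
  expect_true(trc$root$leaf)
  expect_equal(predict(trc, X), rep(5, 4))
  # depth 0: the mean
  tr0 <- fit_cart(X, y, max_depth = 0)
  expect_equal(predict(tr0, X), rep(5, 4))
  expect_error(fit_cart(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("CART equals the exhaustive brute-force oracle", {
  set.seed(202)
  for (t in 1:100) {
    n <- sample(4:25, 1); m <- sample(1:3, 1); depth <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * m), 2), n, m,
                dimnames = list(NULL, paste0("x", 1:m)))
    y <- rnorm(n)
    got <- predict(fit_cart(X, y, max_depth = depth), X)
    want <- cart_oracle_predict(X, y, depth)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("deep CART with distinct rows drives training error to zero", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  tr <- fit_cart(X, y, max_depth = 50)
  expect_lt(mean((predict(tr, X) - y)^2), 1e-20)
})

test_that("poisson cost is available and guarded", {
  X <- matrix(1:8, ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, 1, 2, 2, 9, 9, 10, 10)
  tr <- fit_cart(X, y, max_depth = 1, cost = "poisson")
  expect_equal(tr$root$threshold, 4.5)
  expect_error(fit_cart(X, y - 1, cost = "poisson"), "positive")
})

test_that("forests degenerate to a single tree and are seed-reproducible", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] * 2 + rnorm(30, 0, 0.1)
  one <- fit_forest(X, y, "random_forest", n_estimators = 1, max_depth = 3,
                    mtry = 2, bootstrap = FALSE, seed = 1)
  cart <- fit_cart(X, y, max_depth = 3)
  expect_equal(predict(one, X), predict(cart, X), tolerance = 1e-12)

  f1 <- fit_forest(X, y, "random_forest", n_estimators = 5, seed = 7)
  f2 <- fit_forest(X, y, "random_forest", n_estimators = 5, seed = 7)
  expect_identical(predict(f1, X), predict(f2, X))
  e1 <- fit_forest(X, y, "extra_trees", n_estimators = 5, seed = 7)
  e2 <- fit_forest(X, y, "extra_trees", n_estimators = 5, seed = 7)
  expect_identical(predict(e1, X), predict(e2, X))
  # predictions are means of member trees, hence within the target range
  expect_true(all(predict(e1, X) >= min(y) & predict(e1, X) <= max(y)))
  expect_error(fit_forest(X, y, "extra_trees", subsample = 0), "subsample")
})

test_that("forest prediction is the mean over member trees", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  f <- fit_forest(X, y, "random_forest", n_estimators = 3, seed = 2)
  per_tree <- sapply(f$trees, function(tr) {
    quinoscreen:::.predict_node(tr, X, seq_len(nrow(X)), numeric(nrow(X)))
  })
  expect_equal(predict(f, X), rowMeans(per_tree), tolerance = 1e-12)
})

test_that("gradient boosting follows the residual-fitting recursion", {
  set.seed(13)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(30, 0.5, 0.2)
  m0 <- fit_gbr(X, y, n_estimators = 0)
  expect_equal(predict(m0, X), rep(mean(y), 30))
  # one full-rate unlimited-depth tree absorbs all residuals
  m1 <- fit_gbr(X, y, n_estimators = 1, learning_rate = 1, max_depth = 100)
  expect_lt(mean((predict(m1, X) - y)^2), 1e-20)
  expect_error(fit_gbr(X, y, learning_rate = 0), "learning_rate")
})

test_that("GBR training error is monotone in the number of stages", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- X %*% c(1, -1, 0.5, 0) + rnorm(50, 0, 0.3)
    y <- y[, 1]
    for (gamma in c(0.05, 0.5, 1.0)) {
      fit <- fit_gbr(X, y, n_estimators = 30, learning_rate = gamma,
                     max_depth = 2)
      pred <- rep(fit$f0, 50)
      mses <- numeric(0)
      for (tr in fit$trees) {
        pred <- pred + gamma *
          quinoscreen:::.predict_node(tr, X, 1:50, numeric(50))
        mses <- c(mses, mean((y - pred)^2))
      }
      expect_true(all(diff(mses) <= 1e-12))
    }
  }
})

test_that("feature importances reflect where the cost decreases", {
  X <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  y <- c(0, 0, 10, 10)
  tr <- fit_cart(X, y, max_depth = 1)
  imp <- feature_importances(tr)
  expect_equal(unname(imp["A"]), 1)
  expect_equal(unname(imp["B"]), 0)
  leafy <- fit_cart(X, rep(1, 4), max_depth = 3)
  expect_warning(expect_equal(sum(feature_importances(leafy)), 0), "no splits")
})

test_that("the planted informative feature ranks first in importance", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- cbind(signal = rnorm(80), matrix(rnorm(240), 80, 3))
    colnames(X)[2:4] <- paste0("junk", 1:3)
    y <- 2 * X[, "signal"] + rnorm(80, 0, 0.5)
    f <- fit_forest(X, y, "random_forest", n_estimators = 10, seed = s)
    imp <- feature_importances(f)
    if (names(which.max(imp)) == "signal") hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("JSON serialization round-trips bit-identically", {
  set.seed(21)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(30, 0, 0.2)
  models <- list(fit_ridge(X, y, lambda = 0.1),
                 fit_cart(X, y, max_depth = 3),
                 fit_forest(X, y, "extra_trees", n_estimators = 3, seed = 4),
                 fit_gbr(X, y, n_estimators = 5))
  for (m in models) {
    f <- withr::local_tempfile(fileext = ".json")
    model_to_json(m, f)
    back <- model_from_json(f)
    expect_identical(predict(back, X), predict(m, X))
  }
})

test_that("prediction refuses mismatched columns by name", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_ridge(X, rnorm(10), lambda = 1)
  bad <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "z")))
  expect_error(predict(fit, bad), "missing column.*b")
})

test_that("textual tree export lists splits and leaves", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "x"))
  txt <- tree_export(fit_cart(X, c(0, 0, 10, 10), max_depth = 1))
  expect_match(txt[1], "if x < 2.5")
  expect_length(grep("leaf:", txt), 2)
})

test_that("fits agree with reference implementations within a loose band", {
  set.seed(33)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X %*% c(1, -0.5, 0.25, 0) + rnorm(n, 0, 0.4)
  y <- y[, 1]
  band <- 0.05 * sd(y)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  df <- data.frame(y = y, X)

  ours <- predict(fit_ridge(X, y, lambda = 0), X)
  expect_lt(rmse(ours, predict(lm(y ~ ., df))), band)

  skip_if_not_installed("rpart")
  ref <- predict(rpart::rpart(y ~ ., df, method = "anova",
                              control = rpart::rpart.control(
                                maxdepth = 3, minsplit = 2, minbucket = 1,
                                cp = 0, xval = 0)))
  expect_lt(rmse(predict(fit_cart(X, y, max_depth = 3), X), ref), band)

  # tree ensembles are compared on a tree-representable (piecewise) truth
  # over gapped features, where every implementation recovers the same
  # partition and almost interpolates the training set
  Xg <- matrix(sample(c(-2, -1, 1, 2), n * 3, replace = TRUE), n, 3) +
    matrix(rnorm(n * 3, 0, 0.05), n, 3)
  colnames(Xg) <- paste0("g", 1:3)
  yp <- 2 * (Xg[, 1] > 0) - (Xg[, 2] > 0) + 0.5 * (Xg[, 3] > 0) +
    rnorm(n, 0, 0.05)
  bandp <- 0.05 * sd(yp)
  dfp <- data.frame(y = yp, Xg)

  skip_if_not_installed("randomForest")
  rf <- randomForest::randomForest(Xg, yp, ntree = 300, nodesize = 1)
  ours_rf <- predict(fit_forest(Xg, yp, "random_forest", n_estimators = 300,
                                max_depth = 12, seed = 1), Xg)
  expect_lt(rmse(ours_rf, predict(rf, Xg)), bandp)

  skip_if_not_installed("ranger")
  et <- ranger::ranger(y ~ ., dfp, num.trees = 300, splitrule = "extratrees",
                       replace = FALSE, sample.fraction = 0.8,
                       min.node.size = 1, seed = 1)
  ours_et <- predict(fit_forest(Xg, yp, "extra_trees", n_estimators = 300,
                                max_depth = 12, seed = 1), Xg)
  expect_lt(rmse(ours_et, predict(et, data = dfp)$predictions), bandp)

  skip_if_not_installed("xgboost")
  bst <- xgboost::xgb.train(
    params = list(eta = 0.1, max_depth = 3, objective = "reg:squarederror"),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100)
  ours_gb <- predict(fit_gbr(X, y, n_estimators = 100, learning_rate = 0.1,
                             max_depth = 3), X)
  expect_lt(rmse(ours_gb, predict(bst, X)), band)
})
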