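test_that("split sizes follow the 80/20 floor rule", {
  s <- split_dataset(494, 0.8, seed = 1)
  expect_length(s$train, 395)
  expect_length(s$test, 99)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:494)
  expect_length(split_dataset(10, seed = 2)$train, 8)
  expect_length(split_dataset(5, seed = 3)$train, 4)
  expect_error(split_dataset(10, fraction = 1), "fraction")
  # seeded shuffle: reproducible, seed-sensitive
  expect_identical(split_dataset(100, seed = 4), split_dataset(100, seed = 4))
  expect_false(identical(split_dataset(100, seed = 4)$train,
                         split_dataset(100, seed = 5)$train))
})

test_that("R^2 matches its definition", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(2, 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_error(r_squared(rep(1, 3), y), "zero-variance")
})

test_that("cross-validation is exact on noiseless linear data and seeded", {
  set.seed(17)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + 3
  cv <- cross_validate(model_spec("ridge", lambda = 0), X, y, fold_seed = 2)
  expect_equal(cv$mean_val_r2, 1, tolerance = 1e-9)
  cv2 <- cross_validate(model_spec("ridge", lambda = 0), X, y, fold_seed = 2)
  expect_identical(cv, cv2)
  # folds partition the rows with sizes differing by at most one
  fa <- quinoscreen:::.fold_assignment(53, 5, 1)
  expect_equal(sort(unique(fa)), 1:5)
  expect_lte(diff(range(table(fa))), 1)
  expect_error(cross_validate(model_spec("ridge"), X[1:3, ], y[1:3],
                              folds = 5), "fewer rows")
})

test_that("shuffled labels give near-zero validation R^2", {
  good <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- sample(drop(X %*% c(1, -1, 0.5, 2)))      # break the association
    cv <- cross_validate(model_spec("ridge", lambda = 0), X, y, fold_seed = s)
    if (cv$mean_val_r2 <= 0.1) good <- good + 1
  }
  expect_gte(good, 9)
})

test_that("grid search selects by criterion with regularization-first ties", {
  set.seed(23)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(100, 0, 0.3)
  single <- grid_search("ridge", list(lambda = 0.42), X, y)
  expect_equal(single$best$lambda, 0.42)
  gs <- grid_search("ridge", list(lambda = c(0, 0.1, 1, 10, 100)), X, y)
  # weak sensitivity: selected point is within 0.02 of the grid optimum
  expect_lte(max(gs$results$mean_val_r2) -
               gs$results$mean_val_r2[gs$best_index], 0.02)
  expect_lte(gs$best$lambda, 1)
  # depth grid on depth-3 piecewise data avoids deep overfit
  set.seed(24)
  Xp <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, paste0("x", 1:3)))
  yp <- 2 * (Xp[, 1] > 0) + 1.5 * (Xp[, 2] > 0.5) - (Xp[, 3] > -0.5) +
    rnorm(200, 0, 0.3)
  gd <- grid_search("cart", list(max_depth = 2:20), Xp, yp)
  expect_lte(gd$best$max_depth, 5)
})

test_that("trendline diagnostics behave under shift and scale", {
  set.seed(31)
  ref <- rnorm(50, 1.2, 0.4)
  t1 <- trendline(ref, ref)
  expect_equal(t1$slope, 1, tolerance = 1e-12)
  expect_equal(t1$intercept, 0, tolerance = 1e-12)
  expect_equal(t1$r2, 1, tolerance = 1e-12)
  t2 <- trendline(ref + 0.5, ref)
  expect_equal(t2$slope, 1, tolerance = 1e-12)
  expect_equal(t2$intercept, -0.5, tolerance = 1e-9)
  t3 <- trendline(2 * ref, ref)
  expect_equal(t3$slope, 0.5, tolerance = 1e-12)
  expect_equal(t3$r2, 1, tolerance = 1e-12)
  expect_error(trendline(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("pipeline is reproducible and guards against leakage", {
  base <- small_base()
  ds <- generate_dataset(synthetic_spec(seed = 2, n_scaffolds = 6,
                                        max_substitutions = 1), base = base)
  expect_error(run_pipeline(list(dataset = ds, allow_test_leakage = TRUE)),
               "leakage")
  r1 <- run_pipeline(list(seed = 2, dataset = ds))
  r2 <- run_pipeline(list(seed = 2, dataset = ds))
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$test$ridge$r2, r2$test$ridge$r2)
  expect_identical(r1$predictions, r2$predictions)
  # writes its reports when asked
  out <- withr::local_tempdir()
  run_pipeline(list(seed = 2, dataset = ds, out_dir = out))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "predictions.csv")))
})

test_that("test-set performance tracks cross-validation on synthetic data", {
  base <- default_base()
  ds <- generate_dataset(synthetic_spec(seed = 1), base = base)
  rep <- run_pipeline(list(seed = 1, dataset = ds))
  for (f in names(rep$cv)) {
    expect_lte(abs(rep$test[[f]]$r2 - rep$cv[[f]]$mean_val_r2), 0.15)
  }
})
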