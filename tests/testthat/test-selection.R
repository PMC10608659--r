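test_that("normalization uses the population sd and is idempotent", {
  z <- normalize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd_pop(z), 1, tolerance = 1e-12)
  expect_equal(normalize(z), z, tolerance = 1e-12)
  expect_error(normalize(rep(2, 5)), "constant")
  expect_error(normalize(1), "at least 2")
})

test_that("low-variance filter applies the modal-share threshold inclusively", {
  X <- cbind(const = rep(1, 10),
             six = c(rep(7, 6), 1:4),
             five = c(rep(7, 5), 1:5),
             spread = 1:10)
  r <- low_variance_filter(X)
  expect_setequal(r$removed$column, c("const", "six"))  # 6/10 >= 0.6 removed
  expect_setequal(r$survivors, c("five", "spread"))     # 5/10 < 0.6 kept
})

test_that("target-correlation filter keeps strong and negative predictors", {
  y <- c(1, 2, 3, 4)
  X <- cbind(same = y, neg = -y, orth = c(1, -1, -1, 1), noise = c(2, 1, 4, 3))
  r <- target_correlation_filter(X, y)
  expect_true(all(c("same", "neg") %in% r$survivors))
  expect_true("orth" %in% r$removed$column)              # exactly r = 0
  # signed mode discards the perfect negative predictor
  rs <- target_correlation_filter(X, y, use_absolute = FALSE)
  expect_true("neg" %in% rs$removed$column)
})

test_that("mutual-correlation filter keeps one representative per cluster", {
  set.seed(1)
  y <- rnorm(50)
  a <- y + rnorm(50, 0, 0.3)
  X <- cbind(a = a, b = a, c = a, ind = rnorm(50))
  r <- mutual_correlation_filter(X, y)
  expect_setequal(r$survivors, c("a", "ind"))            # first of the ties
  # a pair at exactly |r| = 0.7 survives ("greater than" is removed)
  n <- 1000
  u <- rnorm(n); v <- rnorm(n)
  u <- normalize(u); v <- normalize(residuals(lm(v ~ u)))
  w <- 0.7 * u + sqrt(1 - 0.49) * v                      # cor(u, w) = 0.7
  X2 <- cbind(u = u, w = w)
  r2 <- mutual_correlation_filter(X2, u + w, threshold = 0.7)
  expect_equal(abs(cor(u, w)), 0.7, tolerance = 1e-9)
  expect_setequal(r2$survivors, c("u", "w"))
})

test_that("backward stepwise drops a pure-noise column first", {
  hits <- 0
  for (s in 1:10) {
    p <- planted_selection_dataset(seed = s, n_noise = 2, n_duplicates = 0,
                                   n_rows = 120)
    X <- p$X[, p$roles != "noise" | colnames(p$X) == "noise1"]
    r <- backward_stepwise(X, p$y, fold_seed = s)
    if (nrow(r$removed) >= 1 && r$removed$column[1] == "noise1") hits <- hits + 1
  }
  expect_gte(hits, 7)          # clear majority of seeds
})

test_that("stepwise limit behaviors", {
  p <- planted_selection_dataset(seed = 2, n_noise = 0, n_duplicates = 0,
                                 n_rows = 80)
  # infinite tolerance removes everything down to the floor
  r <- backward_stepwise(p$X, p$y, tolerance = Inf)
  expect_length(r$survivors, 1)
  # single-column table is a no-op
  one <- p$X[, 1, drop = FALSE]
  r1 <- backward_stepwise(one, p$y)
  expect_identical(r1$survivors, colnames(one))
  expect_equal(nrow(r1$removed), 0)
})

test_that("full selection recovers the planted structure", {
  ok <- 0
  for (s in 1:10) {
    p <- planted_selection_dataset(seed = s)
    rep <- select_descriptors(p$X, p$y, list(fold_seed = s))
    inf_kept <- all(names(p$roles)[p$roles == "informative"] %in% rep$survivors)
    junk_gone <- !any(rep$survivors %in%
                        names(p$roles)[p$roles != "informative"])
    if (inf_kept && junk_gone) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("selection report is a consistent audit trail", {
  p <- planted_selection_dataset(seed = 4)
  rep <- select_descriptors(p$X, p$y, list(fold_seed = 4))
  expect_setequal(c(rep$survivors, rep$removed$column), colnames(p$X))
  expect_true(all(diff(unname(rep$stage_counts)) <= 0))  # counts only shrink
  # stage-3 survivor set is pairwise below the mutual threshold
  X3cols <- setdiff(colnames(p$X),
                    rep$removed$column[rep$removed$stage <= 3])
  C <- abs(cor(p$X[, X3cols]))
  expect_true(all(C[upper.tri(C)] <= 0.7 + 1e-12))
  # deterministic given the same inputs
  rep2 <- select_descriptors(p$X, p$y, list(fold_seed = 4))
  expect_identical(rep$survivors, rep2$survivors)
})

test_that("selection improves or preserves linear-model CV accuracy", {
  wins <- 0
  for (s in 1:10) {
    p <- planted_selection_dataset(seed = s)
    # drop the constant column: OLS on the raw table needs full rank handled
    # by the pseudo-inverse, the comparison is about noise columns
    rep <- select_descriptors(p$X, p$y, list(fold_seed = s))
    full <- cross_validate(model_spec("ridge", lambda = 0),
                           p$X[, colnames(p$X) != "const"], p$y,
                           fold_seed = s)
    seld <- cross_validate(model_spec("ridge", lambda = 0),
                           p$X[, rep$survivors, drop = FALSE], p$y,
                           fold_seed = s)
    if (seld$mean_val_r2 >= full$mean_val_r2) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
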