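#!/usr/bin/env Rscript
# Step 3: grid-search the hyperparameters of the five model families on the
# training rows (ridge penalty by the minimum train-validation gap, the
# tree-based models by maximum validation R^2).  Writes
# results/grid_search.json.  This step is the slow one (a few minutes).

suppressMessages(library(quinoscreen))
seed <- 1L

feats <- read.csv("results/dataset/descriptors.csv")
labels <- read.csv("results/dataset/labels.csv")
X <- as.matrix(feats[, setdiff(colnames(feats), "canonical")])
y <- labels$delta_E_V
sel <- jsonlite::fromJSON("results/selection_report.json")
tr <- sel$split$train
Xs <- X[tr, sel$survivors, drop = FALSE]
ys <- y[tr]
fs <- seed + 1L

gs <- list(
  ridge = grid_search("ridge", list(lambda = c(0.001, 0.01, 0.1, 1, 10, 100)),
                      Xs, ys, criterion = "min_train_val_gap", fold_seed = fs),
  cart = grid_search("cart", list(max_depth = 2:20), Xs, ys, fold_seed = fs),
  random_forest = grid_search("random_forest",
                              list(n_estimators = c(5L, 10L, 15L, 20L)),
                              Xs, ys, max_depth = 3L, seed = seed + 2L,
                              fold_seed = fs),
  extra_trees = grid_search("extra_trees",
                            list(n_estimators = c(5L, 10L, 15L, 20L)),
                            Xs, ys, max_depth = 3L, seed = seed + 2L,
                            fold_seed = fs),
  gradient_boosting = grid_search("gradient_boosting",
                                  list(learning_rate = c(0.05, 0.1, 0.5),
                                       n_estimators = c(25L, 50L)),
                                  Xs, ys, max_depth = 3L, fold_seed = fs))

for (f in names(gs)) {
  cat("==", f, "(criterion:", gs[[f]]$criterion, ")\n")
  print(gs[[f]]$results, digits = 4)
  cat("selected:", paste(names(gs[[f]]$best), unlist(gs[[f]]$best),
                         sep = "=", collapse = ", "), "\n\n")
}
jsonlite::write_json(lapply(gs, function(g) list(results = g$results,
                                                 best = g$best)),
                     "results/grid_search.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
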