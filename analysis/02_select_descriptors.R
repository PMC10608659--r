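#!/usr/bin/env Rscript
# Step 2: split the dataset 80/20 and run the four-stage descriptor
# selection on the training rows only (low-variance, weak target
# correlation, mutual correlation, backward stepwise by 5-fold CV R^2).
# Writes results/selection_report.json.

suppressMessages(library(quinoscreen))
seed <- 1L

feats <- read.csv("results/dataset/descriptors.csv")
labels <- read.csv("results/dataset/labels.csv")
X <- as.matrix(feats[, setdiff(colnames(feats), "canonical")])
y <- labels$delta_E_V

sp <- split_dataset(nrow(X), fraction = 0.8, seed = seed)
cat(sprintf("split: %d train / %d test\n", length(sp$train), length(sp$test)))

rep <- select_descriptors(X[sp$train, ], y[sp$train],
                          list(fold_seed = seed + 1L))
print(rep)
cat("survivors:", paste(rep$survivors, collapse = ", "), "\n")

jsonlite::write_json(
  list(split = sp, stage_counts = as.list(rep$stage_counts),
       survivors = rep$survivors, removed = rep$removed,
       cv_r2 = rep$cv_r2),
  "results/selection_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
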