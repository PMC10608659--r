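# Four-stage descriptor selection: low-variance (mode) removal, weak
# target-correlation removal, mutual-correlation removal, and backward
# stepwise reduction scored by 5-fold cross-validated R^2.

#' Z-score normalization with the population standard deviation
#'
#' `V_norm = (V - mean(V)) / sd_pop(V)` where `sd_pop` divides by `n`.  With
#' this convention the covariance of two normalized vectors equals their
#' Pearson correlation exactly.
#'
#' @param values numeric vector, length >= 2.
#' @return normalized vector (mean 0, population sd 1).
#' @export
normalize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to normalize")
  s <- sd_pop(values)
  if (s == 0) stop("cannot normalize a constant vector (zero variance)")
  (values - mean(values)) / s
}

#' Population standard deviation (divide by n)
#' @param values numeric vector.
#' @return numeric scalar.
#' @export
sd_pop <- function(values) sqrt(mean((values - mean(values))^2))

# Pearson correlation via normalized covariance; 0 when either side is
# constant (such columns are the low-variance filter's job).
.corr <- function(x, y) {
  sx <- sd_pop(x); sy <- sd_pop(y)
  if (sx == 0 || sy == 0) return(0)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
}

.as_matrix <- function(table) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("feature table must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Stage 1: low-variance (mode) filter
#'
#' Removes a column when its modal value accounts for `mode_fraction` or
#' more of the rows.
#'
#' @param table numeric feature table (matrix or data.frame).
#' @param mode_fraction removal threshold on the modal share (default 0.60;
#'   a share exactly equal to the threshold is removed).
#' @return list with `survivors` (column names) and `removed` (data.frame of
#'   column, statistic).
#' @export
low_variance_filter <- function(table, mode_fraction = 0.60) {
  X <- .as_matrix(table)
  share <- apply(X, 2, function(v) max(table(v)) / length(v))
  drop <- share >= mode_fraction
  list(survivors = colnames(X)[!drop],
       removed = data.frame(column = colnames(X)[drop],
                            reason = rep("low_variance", sum(drop)),
                            statistic = unname(share[drop]),
                            stringsAsFactors = FALSE))
}

#' Stage 2: weak target-correlation filter
#'
#' Computes the covariance of the normalized column with the normalized
#' label (equal to the Pearson correlation under the population-sd
#' convention) and removes columns whose correlation is below `threshold`
#' in absolute value (signed mode available); the boundary value is kept.
#'
#' @param table numeric feature table.
#' @param y label vector.
#' @param threshold minimum correlation (default 0.25).
#' @param use_absolute compare `|r|` (default) rather than signed `r`.
#' @return list with `survivors` and `removed` as in
#'   [low_variance_filter()].
#' @export
target_correlation_filter <- function(table, y, threshold = 0.25,
                                      use_absolute = TRUE) {
  if (is.null(y)) stop("label vector required for target-correlation filter")
  X <- .as_matrix(table)
  r <- apply(X, 2, .corr, y = y)
  stat <- if (use_absolute) abs(r) else r
  drop <- stat < threshold
  list(survivors = colnames(X)[!drop],
       removed = data.frame(column = colnames(X)[drop],
                            reason = rep("weak_target_correlation", sum(drop)),
                            statistic = unname(r[drop]),
                            stringsAsFactors = FALSE),
       correlations = r)
}

#' Stage 3: mutual-correlation filter
#'
#' Greedy deduplication of strongly correlated descriptors: columns are
#' ranked by decreasing absolute target correlation (ties broken by column
#' order) and scanned in rank order; a column is kept iff its correlation
#' with every already-kept column does not exceed `threshold` in absolute
#' value (strictly greater is removed, so the boundary survives).
#'
#' @param table numeric feature table.
#' @param y label vector (for the ranking).
#' @param threshold maximum tolerated mutual correlation (default 0.7).
#' @param use_absolute use absolute correlations (default).
#' @return list with `survivors` and `removed`.
#' @export
mutual_correlation_filter <- function(table, y, threshold = 0.7,
                                      use_absolute = TRUE) {
  X <- .as_matrix(table)
  rt <- apply(X, 2, .corr, y = y)
  key <- if (use_absolute) abs(rt) else rt
  ord <- order(-key, seq_len(ncol(X)))
  kept <- integer(0)
  removed <- data.frame(column = character(), reason = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  for (j in ord) {
    if (length(kept)) {
      rr <- vapply(kept, function(k) .corr(X[, j], X[, k]), numeric(1))
      m <- if (use_absolute) max(abs(rr)) else max(rr)
      if (m > threshold) {
        removed <- rbind(removed, data.frame(
          column = colnames(X)[j], reason = "mutual_correlation",
          statistic = m, stringsAsFactors = FALSE))
        next
      }
    }
    kept <- c(kept, j)
  }
  kept <- sort(kept)
  list(survivors = colnames(X)[kept], removed = removed)
}

# 5-fold CV R^2 of an OLS fit (ridge machinery at lambda = 0 with
# pseudo-inverse fallback) used as the stepwise criterion.
.cv_r2_ols <- function(X, y, folds, fold_seed) {
  cv <- cross_validate(model_spec("ridge", lambda = 0), X, y,
                       folds = folds, fold_seed = fold_seed)
  cv$mean_val_r2
}

#' Stage 4: backward stepwise reduction
#'
#' Iteratively drops the column whose removal yields the highest mean
#' 5-fold cross-validated R^2 of a linear model, stopping when the best
#' removal would lower the current CV R^2 by more than `tolerance`, or when
#' `floor_columns` would be violated.
#'
#' @param table numeric feature table (>= 2 columns for any reduction).
#' @param y label vector.
#' @param folds CV folds (default 5).
#' @param tolerance maximum tolerated CV R^2 decrease per removal
#'   (default 0.001).
#' @param fold_seed seed fixing the fold assignment.
#' @param floor_columns minimum number of surviving columns (default 1).
#' @return list with `survivors`, `removed` (with the CV R^2 after each
#'   removal as statistic) and `cv_r2` (final criterion value).
#' @export
backward_stepwise <- function(table, y, folds = 5L, tolerance = 0.001,
                              fold_seed = 1L, floor_columns = 1L) {
  X <- .as_matrix(table)
  cols <- colnames(X)
  removed <- data.frame(column = character(), reason = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  if (ncol(X) < 2) {
    return(list(survivors = cols, removed = removed,
                cv_r2 = if (ncol(X)) .cv_r2_ols(X, y, folds, fold_seed) else NA))
  }
  current <- cols
  cur_r2 <- .cv_r2_ols(X[, current, drop = FALSE], y, folds, fold_seed)
  while (length(current) > floor_columns) {
    cand_r2 <- vapply(current, function(j) {
      keep <- setdiff(current, j)
      .cv_r2_ols(X[, keep, drop = FALSE], y, folds, fold_seed)
    }, numeric(1))
    best <- which.max(cand_r2)           # first max: deterministic tie-break
    if (cand_r2[best] < cur_r2 - tolerance) break
    removed <- rbind(removed, data.frame(
      column = current[best], reason = "backward_stepwise",
      statistic = unname(cand_r2[best]), stringsAsFactors = FALSE))
    current <- setdiff(current, current[best])
    cur_r2 <- cand_r2[best]
  }
  list(survivors = current, removed = removed, cv_r2 = cur_r2)
}

#' Full four-stage descriptor selection
#'
#' Applies the stages in order on a labelled feature table and returns a
#' full audit report.
#'
#' @param table numeric feature table.
#' @param y label vector.
#' @param config list overriding the defaults: `mode_fraction` (0.60),
#'   `target_corr_min` (0.25), `mutual_corr_max` (0.7), `cv_folds` (5),
#'   `stepwise_tolerance` (0.001), `fold_seed` (1), `floor_columns` (1),
#'   `use_absolute_correlations` (TRUE).
#' @return a `selection_report`: list with `survivors`, `removed`
#'   (data.frame with stage, column, reason, statistic), `stage_counts`
#'   (survivor count after each stage) and `cv_r2`.
#' @export
select_descriptors <- function(table, y, config = list()) {
  cfg <- utils::modifyList(list(
    mode_fraction = 0.60, target_corr_min = 0.25, mutual_corr_max = 0.7,
    cv_folds = 5L, stepwise_tolerance = 0.001, fold_seed = 1L,
    floor_columns = 1L, use_absolute_correlations = TRUE), config)
  X <- .as_matrix(table)
  if (is.null(y)) stop("labels are required for descriptor selection")

  s1 <- low_variance_filter(X, cfg$mode_fraction)
  X1 <- X[, s1$survivors, drop = FALSE]
  s2 <- target_correlation_filter(X1, y, cfg$target_corr_min,
                                  cfg$use_absolute_correlations)
  X2 <- X1[, s2$survivors, drop = FALSE]
  s3 <- mutual_correlation_filter(X2, y, cfg$mutual_corr_max,
                                  cfg$use_absolute_correlations)
  X3 <- X2[, s3$survivors, drop = FALSE]
  s4 <- backward_stepwise(X3, y, folds = cfg$cv_folds,
                          tolerance = cfg$stepwise_tolerance,
                          fold_seed = cfg$fold_seed,
                          floor_columns = cfg$floor_columns)
  removed <- rbind(
    cbind(stage = rep(1L, nrow(s1$removed)), s1$removed),
    cbind(stage = rep(2L, nrow(s2$removed)), s2$removed),
    cbind(stage = rep(3L, nrow(s3$removed)), s3$removed),
    cbind(stage = rep(4L, nrow(s4$removed)), s4$removed))
  structure(list(
    survivors = s4$survivors,
    removed = removed,
    stage_counts = c(input = ncol(X), stage1 = length(s1$survivors),
                     stage2 = length(s2$survivors),
                     stage3 = length(s3$survivors),
                     stage4 = length(s4$survivors)),
    cv_r2 = s4$cv_r2,
    config = cfg), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n  survivors per stage: ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = ", "),
      sprintf("\n  final CV R^2: %.4f\n", x$cv_r2))
  invisible(x)
}
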