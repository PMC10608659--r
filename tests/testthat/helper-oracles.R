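# Independent brute-force oracles used by the tests.  These deliberately
# avoid the package's optimized code paths.

# Exhaustive automorphism orbit search: backtracking over all label-
# preserving bijections of the heavy-atom graph (elements, charge, H count,
# aromatic flag, and bond types must match).  Feasible for <= 14 atoms.
brute_force_orbits <- function(mol) {
  n <- nrow(mol$atoms)
  lab <- sprintf("%s/%d/%d/%d", mol$atoms$element, mol$atoms$charge,
                 mol$atoms$nH, as.integer(mol$atoms$aromatic))
  B <- matrix("", n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    t <- if (mol$bonds$aromatic[k]) "a" else as.character(mol$bonds$order[k])
    B[i, j] <- t; B[j, i] <- t
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  map <- integer(n)
  extend <- function(pos) {
    if (pos > n) {
      for (a in seq_len(n)) union_(a, map[a])
      return(invisible(NULL))
    }
    for (cand in seq_len(n)) {
      if (cand %in% map[seq_len(pos - 1)]) next
      if (lab[cand] != lab[pos]) next
      ok <- TRUE
      for (prev in seq_len(pos - 1)) {
        if (B[pos, prev] != B[cand, map[prev]]) { ok <- FALSE; break }
      }
      if (ok) {
        map[pos] <<- cand
        extend(pos + 1)
        map[pos] <<- 0L
      }
    }
  }
  extend(1L)
  vapply(seq_len(n), find, integer(1))
}

# Brute-force derivative enumeration: substitute at EVERY carbon-bound
# hydrogen (not just symmetry representatives), dedup by canonical form.
brute_force_derivatives <- function(mol, substituents) {
  out <- character(0)
  positions <- which(mol$atoms$element == "C" & mol$atoms$nH >= 1)
  for (pos in positions) {
    for (s in substituents) {
      der <- quinoscreen:::attach_substituent(mol, pos, s)
      out <- c(out, canonical_form(der))
    }
  }
  sort(unique(out), method = "radix")
}

# Exhaustive CART oracle: plain recursive search over every feature and
# every midpoint threshold, minimizing summed child SSE directly (no
# cumulative-sum tricks), same tie-break order as the spec (feature order,
# ascending threshold, strict improvement).
cart_oracle_predict <- function(X, y, max_depth, min_leaf = 1L) {
  fit_node <- function(rows, depth) {
    yy <- y[rows]
    if (depth >= max_depth || length(rows) < 2 * min_leaf ||
        var_pop(yy) <= 1e-14) {
      return(list(leaf = TRUE, value = mean(yy)))
    }
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[rows, j]))
      if (length(xs) < 2) next
      for (t in (xs[-length(xs)] + xs[-1]) / 2) {
        l <- rows[X[rows, j] < t]; r <- rows[X[rows, j] >= t]
        if (length(l) < min_leaf || length(r) < min_leaf) next
        sse <- sum((y[l] - mean(y[l]))^2) + sum((y[r] - mean(y[r]))^2)
        if (is.null(best) || sse < best$sse - 1e-12) {
          best <- list(j = j, t = t, sse = sse)
        }
      }
    }
    node_sse <- sum((yy - mean(yy))^2)
    if (is.null(best) || best$sse >= node_sse - 1e-12) {
      return(list(leaf = TRUE, value = mean(yy)))
    }
    list(leaf = FALSE, j = best$j, t = best$t,
         left = fit_node(rows[X[rows, best$j] < best$t], depth + 1),
         right = fit_node(rows[X[rows, best$j] >= best$t], depth + 1))
  }
  var_pop <- function(v) mean((v - mean(v))^2)
  root <- fit_node(seq_len(nrow(X)), 0)
  pred1 <- function(node, row) {
    if (node$leaf) return(node$value)
    if (X[row, node$j] < node$t) pred1(node$left, row) else pred1(node$right, row)
  }
  vapply(seq_len(nrow(X)), function(r) pred1(root, r), numeric(1))
}

# Direct normal-equation ridge oracle (penalty on all coefficients
# including the intercept, matching the fitted closed form).
ridge_oracle <- function(X, y, lambda) {
  X1 <- cbind(1, as.matrix(X))
  solve(t(X1) %*% X1 + lambda * diag(ncol(X1)), t(X1) %*% y)[, 1]
}

# Small fixture molecules shared across test files.
fixture_smiles <- c(
  benzoquinone   = "O=C1C=CC(=O)C=C1",
  naphthoquinone = "O=C1C=CC(=O)c2ccccc12",
  menadione      = "CC1=CC(=O)c2ccccc2C1=O",
  toluene        = "Cc1ccccc1",
  acetonitrile   = "CC#N",
  lawsone        = "OC1=CC(=O)c2ccccc2C1=O",
  propyne        = "CC#C",
  butadiene      = "C=CC=C",
  ethanol        = "CCO"
)
fixture_mols <- function() lapply(fixture_smiles, parse_smiles)

skewness <- function(v) mean((v - mean(v))^3) / sd_pop(v)^3

# Cached deterministic feature base for tests that need the full default
# derivative set (computed once per test run).
.test_cache <- new.env(parent = emptyenv())
default_base <- function() {
  if (is.null(.test_cache$base)) {
    .test_cache$base <- synthetic_feature_base()
  }
  .test_cache$base
}
small_base <- function() {
  if (is.null(.test_cache$small)) {
    .test_cache$small <- synthetic_feature_base(n_scaffolds = 6L,
                                                max_substitutions = 1L)
  }
  .test_cache$small
}
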