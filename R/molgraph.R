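#' @keywords internal
"_PACKAGE"

# Element data used across the package: valence electron count (Zv), principal
# quantum number (pqn), default bonding valence, and monoisotopic-free average
# atomic mass (g/mol).
.ELEMENTS <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  zv      = c(1, 3, 4, 5, 6, 7, 4, 5, 6, 7, 7, 7),
  pqn     = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 5),
  valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 1, 1),
  mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
              28.086, 30.974, 32.065, 35.453, 79.904, 126.904),
  stringsAsFactors = FALSE
)

.element_row <- function(element) {
  idx <- match(element, .ELEMENTS$element)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .ELEMENTS[idx, , drop = FALSE]
}

#' Construct a molecular graph
#'
#' A `molgraph` is the package's molecular substrate: a labelled undirected
#' graph of heavy atoms.  Hydrogens are kept as per-atom attached-H counts
#' rather than explicit nodes.  Bond orders are 1, 2 or 3; aromatic bonds are
#' flagged and carry a nominal order of 1.
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge), `nH` (attached hydrogen count) and `aromatic`
#'   (logical).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical).
#' @param name free-text molecule name.
#' @param validate check the structural invariants (default `TRUE`).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, name = "", validate = TRUE) {
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      nH = as.integer(atoms$nH),
                      aromatic = as.logical(atoms$aromatic),
                      stringsAsFactors = FALSE)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(),
                        order = integer(), aromatic = logical())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order),
                        aromatic = as.logical(bonds$aromatic))
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, name = as.character(name)),
                   class = "molgraph")
  if (validate) validate_molgraph(mol)
  mol
}

#' Validate molecular-graph invariants
#'
#' Checks bond endpoints, self/duplicate bonds, non-negative hydrogen counts
#' and (for molecules entering the pipeline) connectivity.
#'
#' @param mol a `molgraph`.
#' @param require_connected require a single connected component.
#' @return `mol`, invisibly; errors on violation.
#' @export
validate_molgraph <- function(mol, require_connected = TRUE) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (n == 0) stop("molecule has no atoms")
  .element_row(mol$atoms$element)            # errors on unknown elements
  if (any(mol$atoms$nH < 0)) stop("negative attached-H count")
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n)) {
      stop("bond endpoint out of range")
    }
    if (any(b$i == b$j)) stop("self-bond found")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond found")
    if (!all(b$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  if (require_connected && n > 1 && !is_connected(mol)) {
    stop("molecular graph is not connected")
  }
  invisible(mol)
}

n_atoms <- function(mol) nrow(mol$atoms)
n_bonds <- function(mol) nrow(mol$bonds)

# Adjacency list over heavy atoms: integer neighbour indices per atom.
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Heavy-atom degree (sigma connections to heavy atoms).
atom_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  if (n_bonds(mol)) {
    tb <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
    d <- tb
  }
  d
}

# Sum of bond orders at each atom, counting aromatic bonds as 1.5.
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  if (n_bonds(mol)) {
    ord <- ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
    for (k in seq_len(n_bonds(mol))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + ord[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + ord[k]
    }
  }
  s
}

is_connected <- function(mol) {
  n <- n_atoms(mol)
  if (n <= 1) return(TRUE)
  adj <- adjacency_list(mol)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# All-pairs topological distance over heavy atoms (BFS; unweighted).
topo_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Molecular formula of a graph
#'
#' Hill-ordered formula string including attached hydrogens.
#'
#' @param mol a `molgraph`.
#' @return character scalar, e.g. `"C6H4O2"`.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  h <- sum(mol$atoms$nH)
  els <- names(counts)
  # Hill order: C, H, then alphabetical
  rest <- sort(setdiff(els, "C"), method = "radix")
  ordered <- c(intersect("C", els), rest)
  parts <- character(0)
  for (e in ordered) {
    k <- as.integer(counts[[e]])
    parts <- c(parts, paste0(e, if (k > 1) k else ""))
    if (e == "C" && h > 0) {
      parts <- c(parts, paste0("H", if (h > 1) h else ""))
      h <- 0
    }
  }
  if (h > 0) {
    hpart <- paste0("H", if (h > 1) h else "")
    # no carbon present: H sorts alphabetically
    parts <- sort(c(parts, hpart), method = "radix")
  }
  paste(parts, collapse = "")
}

#' Molecular weight (g/mol)
#' @param mol a `molgraph`.
#' @return numeric scalar.
#' @export
mol_weight <- function(mol) {
  sum(.element_row(mol$atoms$element)$mass) + 1.008 * sum(mol$atoms$nH)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d heavy atoms, %d bonds, formula %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x), n_bonds(x), mol_formula(x)))
  invisible(x)
}

# Renumber atoms by permutation `perm`: new index perm[i] ... we define
# result atom k = old atom ord[k] where ord is the inverse permutation.
permute_atoms <- function(mol, perm) {
  stopifnot(length(perm) == n_atoms(mol), !anyDuplicated(perm))
  inv <- order(perm)                       # inv[new] = old
  atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) {
    bonds$i <- perm[bonds$i]
    bonds$j <- perm[bonds$j]
  }
  molgraph(atoms, bonds, mol$name, validate = FALSE)
}
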