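# Canonical labelling via Morgan-style iterative partition refinement with
# branch-and-take-minimum tie-breaking, and automorphism orbit (symmetry
# class) perception via single-atom marking.  The dedup contract is graph
# identity, not any particular external SMILES dialect.

# Locale-independent (C collation) string comparison: all internal string
# orderings use byte order so results do not depend on LC_COLLATE.
.str_lt <- function(a, b) {
  identical(sort(c(a, b), method = "radix")[1], a) && !identical(a, b)
}

# Initial atom invariant strings: element / charge / nH / aromatic / degree.
.atom_invariants <- function(mol, mark = 0L) {
  deg <- atom_degree(mol)
  inv <- sprintf("%s/%d/%d/%d/%d", mol$atoms$element, mol$atoms$charge,
                 mol$atoms$nH, as.integer(mol$atoms$aromatic), deg)
  if (mark > 0L) inv[mark] <- paste0(inv[mark], "/MARK")
  inv
}

# Refine integer ranks until stable.  Rank of an atom combines its current
# rank with the sorted multiset of (bond type, neighbour rank) pairs.
.refine_ranks <- function(mol, init) {
  adj <- adjacency_list(mol)
  bkey <- if (n_bonds(mol)) {
    paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  } else character(0)
  btype <- ifelse(mol$bonds$aromatic, "a", as.character(mol$bonds$order))
  bond_type <- function(a, b) btype[match(paste(min(a, b), max(a, b)), bkey)]
  rank <- match(init, sort(unique(init), method = "radix"))
  repeat {
    sig <- vapply(seq_len(n_atoms(mol)), function(a) {
      nb <- adj[[a]]
      if (!length(nb)) return(sprintf("%06d|", rank[a]))
      pairs <- sort(vapply(nb, function(w)
        sprintf("%s%06d", bond_type(a, w), rank[w]), character(1)),
        method = "radix")
      sprintf("%06d|%s", rank[a], paste(pairs, collapse = ","))
    }, character(1))
    new_rank <- match(sig, sort(unique(sig), method = "radix"))
    if (identical(new_rank, rank)) break
    rank <- new_rank
  }
  rank
}

# Full canonical ranking: refine, then break remaining ties by branching over
# every member of the first smallest non-singleton class and keeping the
# lexicographically smallest emitted string.  Refinement never splits
# automorphic atoms, so branching over a class explores (at worst) the class
# members; automorphic branches emit identical strings.
.canonical_string <- function(mol, init) {
  rank <- .refine_ranks(mol, init)
  tab <- table(rank)
  tied <- as.integer(names(tab)[tab > 1])
  if (!length(tied)) {
    return(list(smiles = write_smiles(mol, rank), rank = rank))
  }
  # choose the smallest tied class, lowest rank first
  sizes <- tab[as.character(tied)]
  cls <- tied[order(sizes, tied)][1]
  members <- which(rank == cls)
  best <- NULL
  for (a in members) {
    init2 <- sprintf("%09d", rank)
    init2[a] <- paste0(init2[a], "/T")
    cand <- .canonical_string(mol, init2)
    if (is.null(best) || .str_lt(cand$smiles, best$smiles)) best <- cand
  }
  best
}

#' Canonical form of a molecule
#'
#' Returns a string that is identical for any atom ordering of the same
#' molecule and distinct for distinct constitutional isomers.  The string is
#' a SMILES in the package's own canonical dialect and re-parses to the same
#' canonical form.
#'
#' @param mol a [molgraph()].
#' @return character scalar.
#' @examples
#' canonical_form(parse_smiles("CCO")) == canonical_form(parse_smiles("OCC"))
#' @export
canonical_form <- function(mol) {
  .canonical_string(mol, .atom_invariants(mol))$smiles
}

#' Atom symmetry classes (automorphism orbits)
#'
#' Two atoms share a class when a graph automorphism respecting element,
#' charge, hydrogen count, aromaticity and bond types maps one onto the
#' other.  Implemented by marked canonicalization: atoms are equivalent iff
#' the canonical form of the molecule with that single atom marked is the
#' same.  Class ids are therefore stable under atom reordering.
#'
#' @param mol a [molgraph()].
#' @return list with `class_id` (integer per atom, 1-based, ordered by the
#'   marked canonical strings) and `n_classes`.
#' @export
symmetry_classes <- function(mol) {
  n <- n_atoms(mol)
  base_rank <- .refine_ranks(mol, .atom_invariants(mol))
  sig <- character(n)
  # atoms in different refinement classes are never automorphic; singleton
  # refinement classes are singleton orbits
  for (cls in unique(base_rank)) {
    members <- which(base_rank == cls)
    if (length(members) == 1L) {
      sig[members] <- sprintf("solo:%09d", cls)
    } else {
      for (a in members) {
        # mark atom a by a charge offset so the mark is part of both the
        # refinement invariants and the emitted string: the canonical string
        # is then the canonical form of the marked graph, and two atoms are
        # automorphic iff their marked canonical forms coincide
        marked <- mol
        marked$atoms$charge[a] <- marked$atoms$charge[a] + 9L
        sig[a] <- canonical_form(marked)
      }
    }
  }
  ids <- match(sig, sort(unique(sig), method = "radix"))
  list(class_id = ids, n_classes = length(unique(ids)))
}
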