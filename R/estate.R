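# Electrotopological-state (E-state) machinery: Kier-Hall intrinsic states,
# atom E-states, a simplified hydrogen E-state, and the atom-type grammar
# (s/d/t/a bond letters) used by the atom-type E-state descriptors.

#' Intrinsic and electrotopological states
#'
#' Kier-Hall intrinsic state `I = ((2/N)^2 * deltaV + 1) / delta` per heavy
#' atom (`N` principal quantum number, `deltaV` valence electrons minus
#' attached hydrogens, `delta` heavy-atom connections) and E-state
#' `S_i = I_i + sum_j (I_i - I_j) / d_ij^2` with `d` the topological distance
#' plus one.  Hydrogen E-states use the Kier-Hall electronegativity
#' `KHE = (deltaV - delta) / N^2` of the bearing heavy atom with the same
#' distance-damped perturbation; they are a simplified H E-state retaining
#' the perturbation structure (bit-parity with any particular descriptor
#' software is not a goal).
#'
#' @param mol a [molgraph()].
#' @return list with vectors `I`, `S`, `KHE`, `HS` (per heavy atom; `HS` is
#'   `NA` for atoms without hydrogens) and scalar `meanI`.
#' @export
intrinsic_states <- function(mol) {
  n <- n_atoms(mol)
  if (n < 2) stop("intrinsic states undefined for a single-heavy-atom molecule")
  info <- .element_row(mol$atoms$element)
  delta <- atom_degree(mol)
  deltav <- info$zv - mol$atoms$nH
  if (any(delta == 0)) stop("isolated heavy atom: intrinsic state undefined")
  I <- ((2 / info$pqn)^2 * deltav + 1) / delta
  D <- topo_distances(mol) + 1
  S <- numeric(n)
  for (i in seq_len(n)) {
    S[i] <- I[i] + sum((I[i] - I[-i]) / D[i, -i]^2)
  }
  khe <- (deltav - delta) / info$pqn^2
  HS <- rep(NA_real_, n)
  hbear <- which(mol$atoms$nH > 0)
  for (i in hbear) {
    HS[i] <- khe[i] + sum((khe[i] - khe[-i]) / D[i, -i]^2)
  }
  list(I = I, S = S, KHE = khe, HS = HS, meanI = mean(I))
}

# Kier-Hall style atom type labels.  Bond letters: s single, d double,
# t triple, a aromatic; H count appended.  Only the types the descriptor
# panel consumes are distinguished; everything else gets a generic label.
atom_types <- function(mol) {
  n <- n_atoms(mol)
  ns <- nd <- nt <- na_ <- integer(n)
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      for (a in c(mol$bonds$i[k], mol$bonds$j[k])) {
        if (mol$bonds$aromatic[k]) na_[a] <- na_[a] + 1L
        else if (mol$bonds$order[k] == 1L) ns[a] <- ns[a] + 1L
        else if (mol$bonds$order[k] == 2L) nd[a] <- nd[a] + 1L
        else nt[a] <- nt[a] + 1L
      }
    }
  }
  el <- mol$atoms$element
  nH <- mol$atoms$nH
  type <- character(n)
  for (a in seq_len(n)) {
    type[a] <- if (el[a] == "C" && nd[a] == 1L && ns[a] == 2L && nH[a] == 0L) "dssC"
    else if (el[a] == "C" && nd[a] == 1L && ns[a] == 1L && nH[a] == 1L) "dsCH"
    else if (el[a] == "C" && nd[a] == 1L && ns[a] == 0L && nH[a] == 2L) "dCH2"
    else if (el[a] == "C" && na_[a] == 2L && ns[a] == 1L && nH[a] == 0L) "aasC"
    else if (el[a] == "C" && na_[a] == 2L && nH[a] == 1L) "aaCH"
    else if (el[a] == "C" && na_[a] == 3L) "aaaC"
    else if (el[a] == "N" && nt[a] == 1L) "tN"
    else if (el[a] == "O" && nd[a] == 1L) "dO"
    else if (el[a] == "O" && ns[a] == 2L && nH[a] == 0L) "ssO"
    else if (el[a] == "O" && ns[a] == 1L && nH[a] == 1L) "sOH"
    else if (el[a] == "N" && na_[a] == 2L && nH[a] == 0L) "aaN"
    else sprintf("%s_s%dd%dt%da%dH%d", el[a], ns[a], nd[a], nt[a], na_[a], nH[a])
  }
  list(type = type, n_single = ns, n_double = nd, n_triple = nt,
       n_aromatic = na_)
}
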