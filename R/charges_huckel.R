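# Partial charges by iterative partial equalization of orbital
# electronegativities (Gasteiger-type PEOE, 8 damped iterations) and the
# Hueckel pi-system surrogate for the LUMO energy.

# PEOE parameters (a, b, c) of the electronegativity polynomial
# chi(q) = a + b q + c q^2, by element and hybridization.
.PEOE <- list(
  "H"     = c(7.17, 6.24, -0.56),
  "C.sp3" = c(7.98, 9.18, 1.88),
  "C.sp2" = c(8.79, 9.32, 1.51),
  "C.sp"  = c(10.39, 9.45, 0.73),
  "N.sp3" = c(11.54, 10.82, 1.36),
  "N.sp2" = c(12.87, 11.15, 0.85),
  "N.sp"  = c(15.68, 11.70, -0.27),
  "O.sp3" = c(14.18, 12.92, 1.39),
  "O.sp2" = c(17.07, 13.79, 0.47),
  "F"     = c(14.66, 13.85, 2.31),
  "Cl"    = c(11.00, 9.69, 1.35),
  "Br"    = c(10.08, 8.47, 1.16),
  "I"     = c(9.90, 7.96, 0.96),
  "S.sp3" = c(10.14, 9.13, 1.38),
  "S.sp2" = c(10.14, 9.13, 1.38),
  "P.sp3" = c(8.90, 8.24, 0.96),
  "B.sp3" = c(7.98, 9.18, 1.88),
  "Si.sp3" = c(7.30, 6.57, 0.66)
)

# Hybridization label per heavy atom from bond pattern.
atom_hybridization <- function(mol) {
  at <- atom_types(mol)
  n <- n_atoms(mol)
  hyb <- character(n)
  for (a in seq_len(n)) {
    hyb[a] <- if (at$n_triple[a] >= 1L || at$n_double[a] >= 2L) "sp"
    else if (at$n_double[a] == 1L || at$n_aromatic[a] >= 2L) "sp2"
    else "sp3"
  }
  hyb
}

#' Gasteiger-type partial charges
#'
#' Iterative partial equalization of orbital electronegativities over the
#' hydrogen-expanded molecular graph; 8 iterations with damping (1/2)^t.
#'
#' @param mol a [molgraph()].
#' @param n_iter iterations (default 8).
#' @return numeric vector of partial charges for the heavy atoms.
#' @export
gasteiger_charges <- function(mol, n_iter = 8L) {
  n <- n_atoms(mol)
  hyb <- atom_hybridization(mol)
  key <- ifelse(mol$atoms$element %in% c("H", "F", "Cl", "Br", "I"),
                mol$atoms$element,
                paste(mol$atoms$element, hyb, sep = "."))
  # expand with explicit hydrogens
  keys <- c(key, rep("H", sum(mol$atoms$nH)))
  edges_i <- mol$bonds$i; edges_j <- mol$bonds$j
  hidx <- n
  for (a in seq_len(n)) {
    if (mol$atoms$nH[a] > 0) {
      for (t in seq_len(mol$atoms$nH[a])) {
        hidx <- hidx + 1L
        edges_i <- c(edges_i, a); edges_j <- c(edges_j, hidx)
      }
    }
  }
  N <- length(keys)
  par <- lapply(keys, function(k) {
    p <- .PEOE[[k]]
    if (is.null(p)) p <- .PEOE[["C.sp3"]]     # fallback for exotic types
    p
  })
  a_ <- vapply(par, `[`, numeric(1), 1)
  b_ <- vapply(par, `[`, numeric(1), 2)
  c_ <- vapply(par, `[`, numeric(1), 3)
  chiplus <- ifelse(keys == "H", 20.02, a_ + b_ + c_)
  q <- numeric(N)
  for (t in seq_len(n_iter)) {
    damp <- 0.5^t
    chi <- a_ + b_ * q + c_ * q^2
    dq <- numeric(N)
    for (k in seq_along(edges_i)) {
      i <- edges_i[k]; j <- edges_j[k]
      if (chi[j] > chi[i]) {
        d <- (chi[j] - chi[i]) / chiplus[i] * damp
        dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
      } else {
        d <- (chi[i] - chi[j]) / chiplus[j] * damp
        dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
      }
    }
    q <- q + dq
  }
  q[seq_len(n)]
}

# Hueckel alpha/beta (eV) and heteroatom h (alpha shift) / k (bond factor)
# parameters in the Streitwieser convention.  Atoms donating two pi
# electrons (ether/ester O, pyrrole-type N, halogens on the pi system) get
# larger h and a reduced bond factor.
.HUCKEL <- list(alpha = -6.6, beta = -2.7,
                h = c(C = 0, N1 = 0.5, N2 = 1.5, O1 = 1.0, O2 = 2.0, S1 = 0.5),
                k2 = 0.8)

#' Hueckel pseudo-LUMO energy (eV)
#'
#' Builds a topological Hueckel Hamiltonian over the conjugated pi system
#' (aromatic atoms plus atoms engaged in double or triple bonds), diagonal
#' `alpha + h beta` with standard heteroatom `h` values, off-diagonal
#' `k beta` on bonds between pi atoms, fills the levels with the pi
#' electrons and returns the energy of the lowest unoccupied level.  This is
#' a deterministic surrogate for a semi-empirical LUMO and is labelled
#' pseudo-LUMO throughout; externally computed LUMO values can be supplied
#' to [compute_descriptor_table()] instead.
#'
#' @param mol a [molgraph()].
#' @param alpha,beta Coulomb and resonance parameters in eV.
#' @return LUMO energy in eV, or `NA` when the molecule has no pi system.
#' @export
pseudo_lumo <- function(mol, alpha = .HUCKEL$alpha, beta = .HUCKEL$beta) {
  at <- atom_types(mol)
  is_pi <- (mol$atoms$aromatic | at$n_double >= 1L | at$n_triple >= 1L) &
    mol$atoms$element %in% c("C", "N", "O", "S")
  # two-electron donors attached to the pi system (ether O, amine N bonded
  # to a pi atom) are part of the conjugated system as well
  adj <- adjacency_list(mol)
  repeat {
    grew <- FALSE
    for (a in seq_len(n_atoms(mol))) {
      if (!is_pi[a] && mol$atoms$element[a] %in% c("N", "O", "S") &&
          any(is_pi[adj[[a]]])) {
        is_pi[a] <- TRUE; grew <- TRUE
      }
    }
    if (!grew) break
  }
  piatoms <- which(is_pi)
  if (length(piatoms) < 2) return(NA_real_)

  # per-atom h parameter and pi-electron contribution
  h <- numeric(length(piatoms)); ne <- integer(length(piatoms))
  two_e <- logical(length(piatoms))
  for (t in seq_along(piatoms)) {
    a <- piatoms[t]
    el <- mol$atoms$element[a]
    multiple <- at$n_double[a] >= 1L || at$n_triple[a] >= 1L
    if (el == "C") { h[t] <- 0; ne[t] <- 1L }
    else if (el == "N") {
      if (multiple || (mol$atoms$aromatic[a] && mol$atoms$nH[a] == 0L)) {
        h[t] <- .HUCKEL$h[["N1"]]; ne[t] <- 1L
      } else { h[t] <- .HUCKEL$h[["N2"]]; ne[t] <- 2L; two_e[t] <- TRUE }
    } else if (el == "O") {
      if (multiple) { h[t] <- .HUCKEL$h[["O1"]]; ne[t] <- 1L }
      else { h[t] <- .HUCKEL$h[["O2"]]; ne[t] <- 2L; two_e[t] <- TRUE }
    } else {                                      # S
      h[t] <- .HUCKEL$h[["S1"]]
      if (multiple) ne[t] <- 1L else { ne[t] <- 2L; two_e[t] <- TRUE }
    }
  }
  m <- length(piatoms)
  H <- matrix(0, m, m)
  diag(H) <- alpha + h * beta
  pos <- match(seq_len(n_atoms(mol)), piatoms)
  for (k in seq_len(n_bonds(mol))) {
    i <- pos[mol$bonds$i[k]]; j <- pos[mol$bonds$j[k]]
    if (is.na(i) || is.na(j)) next
    kfac <- if (two_e[i] || two_e[j]) .HUCKEL$k2 else 1.0
    H[i, j] <- H[j, i] <- kfac * beta
  }
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  nel <- sum(ne)
  lumo_idx <- nel %/% 2L + 1L
  if (lumo_idx > m) return(NA_real_)
  ev[lumo_idx]
}

#' Burden-matrix BCUT descriptors weighted by partial charge
#'
#' Burden connectivity matrix with Gasteiger partial charges on the
#' diagonal; off-diagonal entries are 0.1 x bond order (1.5 for aromatic),
#' plus 0.01 when either endpoint is terminal, and 0.001 for non-bonded
#' pairs.  Returns the lowest and highest eigenvalues.
#'
#' @param mol a [molgraph()].
#' @param charges optional precomputed diagonal (defaults to
#'   [gasteiger_charges()]).
#' @return named numeric vector `c(BCUTc.1l, BCUTc.1h)`.
#' @export
bcut_extremes <- function(mol, charges = NULL) {
  n <- n_atoms(mol)
  if (is.null(charges)) charges <- gasteiger_charges(mol)
  B <- matrix(0.001, n, n)
  deg <- atom_degree(mol)
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      w <- 0.1 * (if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k])
      if (deg[i] == 1L || deg[j] == 1L) w <- w + 0.01
      B[i, j] <- B[j, i] <- w
    }
  }
  diag(B) <- charges
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  c(BCUTc.1l = min(ev), BCUTc.1h = max(ev))
}
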