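# The 32-descriptor panel: topological, electrotopological and surrogate
# electronic descriptors computed from the molecular graph.

#' Descriptor registry
#'
#' Fixed names and column order of the descriptor panel.
#' @return character vector of 32 descriptor names.
#' @export
descriptor_names <- function() {
  c("BCUTc.1l", "BCUTc.1h", "nBondsD2", "C1SP1", "C3SP2", "ECCEN",
    "nHother", "ndssC", "naasC", "ntN", "SwHBa", "SHdsCH", "SHother",
    "SdssC", "SaasC", "StN", "minHother", "minaasC", "mindO", "maxHother",
    "maxaasC", "meanI", "MAXDN2", "MAXDP2", "fragC", "nRing",
    "topoDiameter", "JGI2", "TopoPSA", "VABC", "MW", "LUMO")
}

# Zhao et al. atomic van der Waals volume contributions (A^3).
.VABC_ATOM <- c(H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31,
                Cl = 22.45, Br = 26.52, I = 32.52, P = 24.43, S = 24.43,
                Si = 38.79, B = 40.48)

# Ertl TPSA fragment contributions (A^2) keyed by the atom_types() labels.
.TPSA <- c(tN = 23.79, dO = 17.07, ssO = 9.23, sOH = 20.23, aaN = 12.89,
           N_s1d1t0a0H0 = 12.36,        # =N-
           N_s3d0t0a0H0 = 3.24,         # -N<
           N_s2d0t0a0H1 = 12.03,        # -NH-
           N_s1d0t0a0H2 = 26.02,        # -NH2
           O_a = 13.14,                 # aromatic o
           S_d = 32.09, S_ss = 25.30)

#' Van der Waals volume (Zhao bond/ring-corrected sum)
#'
#' `V = sum(atom contributions) - 5.92 Nb - 14.7 Ra - 3.8 Rnr` where `Nb`
#' counts all bonds (including bonds to hydrogen) and `Ra`/`Rnr` count
#' aromatic and non-aromatic rings.
#'
#' @param mol a [molgraph()].
#' @return volume in cubic Angstrom, or `NA` for elements outside the table.
#' @export
vabc_volume <- function(mol) {
  contrib <- .VABC_ATOM[mol$atoms$element]
  if (anyNA(contrib)) return(NA_real_)
  nb <- n_bonds(mol) + sum(mol$atoms$nH)
  rings <- .ring_counts(mol)
  sum(contrib) + 7.24 * sum(mol$atoms$nH) -
    5.92 * nb - 14.7 * rings$aromatic - 3.8 * rings$nonaromatic
}

# Ring counts: total = circuit rank; aromatic = number of all-aromatic
# 6-cycles; non-aromatic = remainder (floored at zero).
.ring_counts <- function(mol) {
  total <- n_bonds(mol) - n_atoms(mol) + 1L
  if (total <= 0L) return(list(total = 0L, aromatic = 0L, nonaromatic = 0L))
  cycles <- .find_cycles(mol, max_len = 6L)
  narom <- 0L
  for (cyc in cycles) {
    if (length(cyc) == 6L && all(mol$atoms$aromatic[cyc])) narom <- narom + 1L
  }
  narom <- min(narom, total)
  list(total = total, aromatic = narom, nonaromatic = total - narom)
}

# Galvez topological charge index of order two (mean form).
.jgi2 <- function(mol) {
  n <- n_atoms(mol)
  if (n < 3 || !n_bonds(mol)) return(0)
  D <- topo_distances(mol)
  A <- matrix(0, n, n)
  for (k in seq_len(n_bonds(mol))) {
    A[mol$bonds$i[k], mol$bonds$j[k]] <- 1
    A[mol$bonds$j[k], mol$bonds$i[k]] <- 1
  }
  Dstar <- ifelse(D > 0 & is.finite(D), 1 / D^2, 0)
  M <- A %*% Dstar
  CT <- M - t(M)
  g2 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(D[i, j]) && D[i, j] == 2) g2 <- g2 + abs(CT[i, j])
  }
  g2 / (n - 1)
}

#' Compute the full descriptor panel for one molecule
#'
#' @param mol a [molgraph()].
#' @param lumo optional externally supplied LUMO value (eV); when `NULL` the
#'   Hueckel [pseudo_lumo()] surrogate is used.
#' @return named list with `values` (named numeric, registry order) and
#'   `missing` (named logical flags for descriptors that were undefined and
#'   emitted as 0).
#' @export
compute_descriptors <- function(mol, lumo = NULL) {
  vals <- stats::setNames(numeric(length(descriptor_names())),
                          descriptor_names())
  miss <- stats::setNames(logical(length(descriptor_names())),
                          descriptor_names())
  at <- atom_types(mol)
  st <- intrinsic_states(mol)
  deg <- atom_degree(mol)
  D <- topo_distances(mol)
  ecc <- apply(D, 1, max)

  # electronic block
  bc <- bcut_extremes(mol)
  vals["BCUTc.1l"] <- bc[["BCUTc.1l"]]
  vals["BCUTc.1h"] <- bc[["BCUTc.1h"]]
  lu <- if (!is.null(lumo)) lumo else pseudo_lumo(mol)
  if (is.na(lu)) { miss["LUMO"] <- TRUE; lu <- 0 }
  vals["LUMO"] <- lu

  # simple counts and topology
  vals["nBondsD2"] <- sum(mol$bonds$order == 2L & !mol$bonds$aromatic)
  is_c <- mol$atoms$element == "C"
  adj <- adjacency_list(mol)
  ncarbon_nb <- vapply(adj, function(nb) sum(is_c[nb]), integer(1))
  vals["C1SP1"] <- sum(is_c & at$n_triple >= 1L & ncarbon_nb == 1L)
  vals["C3SP2"] <- sum(is_c & at$n_double == 1L & ncarbon_nb == 3L)
  vals["ECCEN"] <- sum(ecc * deg)
  vals["topoDiameter"] <- max(ecc)
  rings <- .ring_counts(mol)
  vals["nRing"] <- rings$total
  vals["JGI2"] <- .jgi2(mol)
  nhet <- sum(!is_c)
  vals["fragC"] <- abs(n_bonds(mol)^2 - n_atoms(mol)^2 + n_atoms(mol)) +
    nhet / 100
  vals["MW"] <- mol_weight(mol)
  vb <- vabc_volume(mol)
  if (is.na(vb)) { miss["VABC"] <- TRUE; vb <- 0 }
  vals["VABC"] <- vb

  # TPSA from atom-type contributions
  tpsa <- 0
  for (a in seq_len(n_atoms(mol))) {
    ty <- at$type[a]
    el <- mol$atoms$element[a]
    contrib <- if (el == "O" && mol$atoms$aromatic[a]) .TPSA[["O_a"]]
    else if (el == "S" && at$n_double[a] == 1L) .TPSA[["S_d"]]
    else if (el == "S" && at$n_single[a] == 2L) .TPSA[["S_ss"]]
    else if (!is.na(.TPSA[ty])) .TPSA[[ty]]
    else 0
    tpsa <- tpsa + contrib
  }
  vals["TopoPSA"] <- tpsa

  # intrinsic-state block
  vals["meanI"] <- st$meanI
  dI <- vapply(seq_len(n_atoms(mol)), function(a) {
    sum(st$I[a] - st$I[adj[[a]]])
  }, numeric(1))
  vals["MAXDP2"] <- max(c(dI, 0))
  vals["MAXDN2"] <- max(c(-dI, 0))

  # atom-type E-state block
  ty <- at$type
  dssC <- which(ty == "dssC"); aasC <- which(ty == "aasC")
  tN <- which(ty == "tN"); dO <- which(ty == "dO")
  hother <- which(ty %in% c("aaCH", "dCH2", "dsCH"))
  dsCH <- which(ty == "dsCH")
  vals["ndssC"] <- length(dssC)
  vals["naasC"] <- length(aasC)
  vals["ntN"] <- length(tN)
  vals["nHother"] <- sum(mol$atoms$nH[hother])
  vals["SdssC"] <- sum(st$S[dssC])
  vals["SaasC"] <- sum(st$S[aasC])
  vals["StN"] <- sum(st$S[tN])
  # H E-state sums count each hydrogen on the bearing atom
  vals["SHdsCH"] <- sum(st$HS[dsCH] * mol$atoms$nH[dsCH])
  vals["SHother"] <- sum(st$HS[hother] * mol$atoms$nH[hother])
  set_minmax <- function(name, values) {
    if (length(values)) vals[name] <<- values
    else { vals[name] <<- 0; miss[name] <<- TRUE }
  }
  set_minmax("minHother", if (length(hother)) min(st$HS[hother]) else numeric(0))
  set_minmax("maxHother", if (length(hother)) max(st$HS[hother]) else numeric(0))
  set_minmax("minaasC", if (length(aasC)) min(st$S[aasC]) else numeric(0))
  set_minmax("maxaasC", if (length(aasC)) max(st$S[aasC]) else numeric(0))
  set_minmax("mindO", if (length(dO)) min(st$S[dO]) else numeric(0))

  # weak hydrogen-bond acceptors: N/O atoms carrying no hydrogen (carbonyl
  # and ether oxygens, nitrile and aromatic nitrogens); the membership rule
  # is deliberately simple and exposed here as the package's definition
  hba <- which(mol$atoms$element %in% c("N", "O") & mol$atoms$nH == 0L)
  vals["SwHBa"] <- sum(st$S[hba])

  list(values = vals, missing = miss)
}

#' Descriptor table for a set of molecules
#'
#' One row per molecule with the registry columns in fixed order, a leading
#' `canonical` id column and trailing `na_*` missing-flag columns for
#' descriptors that can be undefined.
#'
#' @param mols list of [molgraph()] (or a `derivative_set`).
#' @param lumo optional named numeric vector of externally computed LUMO
#'   values keyed by canonical form (eV); molecules not named fall back to
#'   the Hueckel surrogate.
#' @return data.frame.
#' @export
compute_descriptor_table <- function(mols, lumo = NULL) {
  if (inherits(mols, "derivative_set")) mols <- mols$molecules
  flaggable <- c("LUMO", "VABC", "minHother", "maxHother", "minaasC",
                 "maxaasC", "mindO")
  nm <- descriptor_names()
  if (!length(mols)) {
    tab <- as.data.frame(stats::setNames(
      c(list(character(0)), replicate(length(nm), numeric(0), simplify = FALSE),
        replicate(length(flaggable), logical(0), simplify = FALSE)),
      c("canonical", nm, paste0("na_", flaggable))))
    return(tab)
  }
  rows <- lapply(mols, function(m) {
    cf <- canonical_form(m)
    lu <- if (!is.null(lumo) && cf %in% names(lumo)) lumo[[cf]] else NULL
    d <- compute_descriptors(m, lumo = lu)
    cbind(data.frame(canonical = cf, stringsAsFactors = FALSE),
          as.data.frame(as.list(d$values)),
          stats::setNames(as.data.frame(as.list(d$missing[flaggable])),
                          paste0("na_", flaggable)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
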