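# Free-energy bookkeeping and Nernst conversion for the two-electron,
# two-lithium reduction labels.  Internal energy unit is J/mol; readers
# accept hartree and eV with explicit unit tags.

#' Physical constants used by the thermochemistry module
#' @format list with `R` (J/(mol K)), `F` (C/mol), `hartree` and `eV`
#'   (J/mol per unit).
#' @export
thermo_constants <- function() {
  list(R = 8.31446, F = 96485.332, hartree = 2625499.6, eV = 96485.332)
}

#' Construct a species thermochemistry record
#'
#' Components of the enthalpy/entropy decomposition of one species: total
#' electronic energy `E0`, unscaled zero-point energy `ZPE`, translational /
#' rotational / vibrational enthalpy shares, and translational / rotational /
#' vibrational / electronic entropy contributions.
#'
#' @param id species identifier.
#' @param E0,ZPE,H_trans,H_rot,H_vib energies (J/mol unless `units` says
#'   otherwise).
#' @param S_trans,S_rot,S_vib,S_el entropies (J/(mol K)).
#' @param T temperature in K (default 298).
#' @param units one of `"J/mol"`, `"hartree"`, `"eV"`; energy fields are
#'   converted to J/mol on ingest (entropies are always J/(mol K)).
#' @return a `thermo_record` list.
#' @export
thermo_record <- function(id, E0 = 0, ZPE = 0, H_trans = 0, H_rot = 0,
                          H_vib = 0, S_trans = 0, S_rot = 0, S_vib = 0,
                          S_el = 0, T = 298, units = "J/mol") {
  k <- switch(units, "J/mol" = 1, hartree = thermo_constants()$hartree,
              eV = thermo_constants()$eV,
              stop("unknown unit tag: ", units))
  if (T <= 0) stop("temperature must be positive")
  rec <- list(id = id, E0 = E0 * k, ZPE = ZPE * k, H_trans = H_trans * k,
              H_rot = H_rot * k, H_vib = H_vib * k, S_trans = S_trans,
              S_rot = S_rot, S_vib = S_vib, S_el = S_el, T = T)
  if (!all(vapply(rec[-1], is.finite, logical(1)))) {
    stop("non-finite thermochemistry component for species ", id)
  }
  structure(rec, class = "thermo_record")
}

#' Gibbs free energy of a species
#'
#' `H = E0 + ZPE + H_trans + H_rot + H_vib + R T`,
#' `S = S_trans + S_rot + S_vib + S_el`, `G = H - T S`.
#'
#' @param rec a [thermo_record()].
#' @return named list with `H`, `S`, `G` (J/mol, J/(mol K), J/mol).
#' @export
gibbs_free_energy <- function(rec) {
  R <- thermo_constants()$R
  H <- rec$E0 + rec$ZPE + rec$H_trans + rec$H_rot + rec$H_vib + R * rec$T
  S <- rec$S_trans + rec$S_rot + rec$S_vib + rec$S_el
  list(H = H, S = S, G = H - rec$T * S)
}

#' Reaction free energy of the two-lithium reduction
#'
#' `deltaG = G_reduced - G_oxidized - 2 G_Li` for the reaction
#' quinone + 2 Li -> Li2(quinone).
#'
#' @param G_reduced,G_oxidized,G_Li Gibbs free energies in J/mol.
#' @return deltaG in J/mol.
#' @export
reaction_free_energy <- function(G_reduced, G_oxidized, G_Li) {
  stopifnot(is.finite(G_reduced), is.finite(G_oxidized), is.finite(G_Li))
  G_reduced - G_oxidized - 2 * G_Li
}

#' Redox potential from the Nernst equation
#'
#' `deltaE = -deltaG / (n F)` with `F` the Faraday constant.
#'
#' @param deltaG reaction free energy in J/mol.
#' @param n number of exchanged electrons (default 2).
#' @return potential in volts.
#' @export
redox_potential <- function(deltaG, n = 2L) {
  if (n < 1) stop("number of exchanged electrons must be >= 1")
  -deltaG / (n * thermo_constants()$F)
}

#' Read species thermochemistry records from JSON
#'
#' One record per species: `{"id", "units", "E0", "ZPE", "H_trans", ...}`.
#'
#' @param path JSON file (array of objects).
#' @return list of [thermo_record()].
#' @export
read_thermo_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    do.call(thermo_record, r)
  })
}

#' Write species thermochemistry records to JSON
#' @param records list of [thermo_record()].
#' @param path output file.
#' @export
write_thermo_json <- function(records, path) {
  out <- lapply(records, function(r) {
    c(list(units = "J/mol"), unclass(r))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}
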