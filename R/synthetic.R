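# Synthetic datasets with the statistical structure the analysis assumes:
# quinone derivative sets with descriptors, redox labels emulating a
# DFT-derived distribution (asymmetric bell, bulk between 0.75 and 1.60 V
# inside 0.3-2.8 V), and thermochemistry records exactly consistent with
# the labels through the free-energy bookkeeping.

#' Specification of the synthetic dataset generator
#'
#' The defaults define the study conditions: derivatives of the first
#' `n_scaffolds` bundled quinone scaffolds with up to two substituents
#' (about 500 molecules), and a predominantly linear structure-potential
#' relationship
#' `deltaE = b0 + b_CN n_CN + b_alk n_alk + b_L LUMO + noise`, clipped to
#' the physical range.
#'
#' @param seed RNG seed.
#' @param n_scaffolds number of bundled scaffolds used (default 12).
#' @param max_substitutions substituents per derivative (default 2).
#' @param b0 intercept (V).
#' @param b_CN per-cyano effect (V).
#' @param b_alk per-alkynyl effect (V).
#' @param b_L pseudo-LUMO coefficient (V/eV, negative: lower LUMO means
#'   higher potential).
#' @param sigma label noise sd (V).
#' @param clip allowed label range (V).
#' @param nonlinear add an interaction term `b_CN/2 * n_CN * LUMO-center`
#'   for contrast experiments (default `FALSE`).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_scaffolds = 12L,
                           max_substitutions = 2L, b0 = -2.98, b_CN = 0.55,
                           b_alk = 0.12, b_L = -0.50, sigma = 0.22,
                           clip = c(0.3, 2.8), nonlinear = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (clip[1] >= clip[2]) stop("clip range must satisfy low < high")
  structure(list(seed = seed, n_scaffolds = n_scaffolds,
                 max_substitutions = max_substitutions, b0 = b0,
                 b_CN = b_CN, b_alk = b_alk, b_L = b_L, sigma = sigma,
                 clip = clip, nonlinear = nonlinear),
            class = "synthetic_spec")
}

#' Deterministic feature base of the synthetic generator
#'
#' Enumerates the derivative set of the bundled scaffolds and computes the
#' descriptor table plus substituent counts.  This part involves no
#' randomness, so it can be computed once and shared across seeds.
#'
#' @param n_scaffolds,max_substitutions as in [synthetic_spec()].
#' @return list with `derivatives`, `features` (descriptor data.frame) and
#'   `counts` (data.frame with `n_CN`, `n_alk`).
#' @export
synthetic_feature_base <- function(n_scaffolds = 12L,
                                   max_substitutions = 2L) {
  scaffolds <- builtin_scaffolds()
  if (!length(scaffolds)) stop("empty scaffold fixture set")
  n_scaffolds <- min(n_scaffolds, length(scaffolds))
  ders <- enumerate_derivatives(scaffolds[seq_len(n_scaffolds)],
                                max_substitutions = max_substitutions)
  feats <- compute_descriptor_table(ders)
  subs <- strsplit(ders$manifest$substituents, "+", fixed = TRUE)
  counts <- data.frame(
    n_CN = vapply(subs, function(s) sum(s == "CN"), integer(1)),
    n_alk = vapply(subs, function(s) sum(s == "CCMe"), integer(1)))
  list(derivatives = ders, features = feats, counts = counts)
}

# fixed bookkeeping constants for the back-solved thermochemistry (J/mol):
# gas-phase lithium free energy and a size-dependent baseline for the
# oxidized species
.G_LI <- -7.49 * 2625499.6
.g_oxidized <- function(natoms) -(40 + natoms) * 2625499.6 / 10

#' Generate a synthetic screening dataset
#'
#' Derivatives come from the bundled scaffolds via the enumeration module,
#' descriptors from the descriptor engine, labels from the linear ground
#' truth of the spec plus Gaussian noise (clipped to the physical range,
#' clip events are counted), and thermochemistry records are back-solved so
#' that the free-energy arithmetic reproduces every label exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param base optional precomputed [synthetic_feature_base()] (must match
#'   the spec's scaffold settings).
#' @return list of class `synthetic_dataset` with `features`, `labels`
#'   (canonical, delta_E_V, n_CN, n_alk), `thermo` (records for oxidized /
#'   reduced species and lithium), `truth` (generator coefficients) and
#'   `n_clipped`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), base = NULL) {
  if (is.null(base)) {
    base <- synthetic_feature_base(spec$n_scaffolds, spec$max_substitutions)
  }
  feats <- base$features
  n <- nrow(feats)
  lumo <- feats$LUMO
  mu <- spec$b0 + spec$b_CN * base$counts$n_CN +
    spec$b_alk * base$counts$n_alk + spec$b_L * lumo
  if (spec$nonlinear) {
    mu <- mu + (spec$b_CN / 2) * base$counts$n_CN * (lumo - mean(lumo))
  }
  y <- .with_seed(spec$seed, mu + stats::rnorm(n, 0, spec$sigma))
  n_clipped <- sum(y < spec$clip[1] | y > spec$clip[2])
  y <- pmin(pmax(y, spec$clip[1]), spec$clip[2])

  labels <- data.frame(canonical = feats$canonical, delta_E_V = y,
                       n_CN = base$counts$n_CN, n_alk = base$counts$n_alk,
                       stringsAsFactors = FALSE)

  F_ <- thermo_constants()$F
  thermo <- vector("list", 2 * n + 1)
  mk_record <- function(id, G_target, natoms) {
    # realistic-looking components; E0 absorbs the remainder so that the
    # free-energy arithmetic reproduces G_target exactly
    T <- 298
    ZPE <- 3.0e5 + 2.2e4 * natoms
    H_trans <- 3718.5; H_rot <- 3718.5; H_vib <- 1.2e4 + 900 * natoms
    S <- c(S_trans = 165, S_rot = 110, S_vib = 40 + 6 * natoms, S_el = 0)
    R <- thermo_constants()$R
    E0 <- G_target + T * sum(S) - (ZPE + H_trans + H_rot + H_vib + R * T)
    thermo_record(id, E0 = E0, ZPE = ZPE, H_trans = H_trans, H_rot = H_rot,
                  H_vib = H_vib, S_trans = S[["S_trans"]],
                  S_rot = S[["S_rot"]], S_vib = S[["S_vib"]],
                  S_el = S[["S_el"]], T = T)
  }
  mols <- base$derivatives$molecules
  for (i in seq_len(n)) {
    na <- n_atoms(mols[[i]])
    G_i <- .g_oxidized(na)
    G_ii <- G_i + 2 * .G_LI - 2 * F_ * y[i]
    thermo[[2 * i - 1]] <- mk_record(paste0(feats$canonical[i], ":ox"),
                                     G_i, na)
    thermo[[2 * i]] <- mk_record(paste0(feats$canonical[i], ":red"),
                                 G_ii, na + 2)
  }
  thermo[[2 * n + 1]] <- mk_record("Li", .G_LI, 1)

  structure(list(features = feats, labels = labels, thermo = thermo,
                 truth = spec, n_clipped = n_clipped,
                 manifest = base$derivatives$manifest),
            class = "synthetic_dataset")
}

#' Recompute labels from the thermochemistry records of a dataset
#'
#' Runs each oxidized/reduced record pair through the Gibbs free-energy
#' decomposition, the two-lithium reaction free energy and the Nernst
#' conversion; used to verify the round-trip invariant.
#'
#' @param ds a [generate_dataset()] result.
#' @return numeric vector of potentials (V), aligned with `ds$labels`.
#' @export
recompute_labels_from_thermo <- function(ds) {
  ids <- vapply(ds$thermo, function(r) r$id, character(1))
  G <- vapply(ds$thermo, function(r) gibbs_free_energy(r)$G, numeric(1))
  G_li <- G[ids == "Li"]
  vapply(seq_len(nrow(ds$labels)), function(i) {
    cf <- ds$labels$canonical[i]
    dG <- reaction_free_energy(G[ids == paste0(cf, ":red")],
                               G[ids == paste0(cf, ":ox")], G_li)
    redox_potential(dG, n = 2L)
  }, numeric(1))
}

#' Planted dataset for the selection-pipeline acceptance harness
#'
#' Informative columns enter the label linearly (unit weights, noise sd
#' 0.5); noise columns are independent of the label and the first one is
#' constant; duplicate columns copy informative ones (exactly by default,
#' or with correlation about `duplicate_r`).
#'
#' @param seed RNG seed.
#' @param n_informative,n_noise,n_duplicates,n_rows layout (defaults 5,
#'   10, 5, 300).
#' @param duplicate_r target correlation of duplicates with their source
#'   (1 = exact copy).
#' @return list with `X` (named matrix), `y`, and `roles` (character per
#'   column: informative / noise / duplicate).
#' @export
planted_selection_dataset <- function(seed = 1L, n_informative = 5L,
                                      n_noise = 10L, n_duplicates = 5L,
                                      n_rows = 300L, duplicate_r = 1) {
  if (n_rows <= n_informative + 2L) stop("n_rows too small")
  .with_seed(seed, {
    Xi <- matrix(stats::rnorm(n_rows * n_informative), n_rows)
    colnames(Xi) <- paste0("inf", seq_len(n_informative))
    y <- rowSums(Xi) + stats::rnorm(n_rows, 0, 0.5)
    Xn <- NULL
    if (n_noise > 0) {
      Xn <- cbind(const = rep(1, n_rows),
                  if (n_noise > 1)
                    matrix(stats::rnorm(n_rows * (n_noise - 1)), n_rows))
      colnames(Xn) <- c("const", if (n_noise > 1)
        paste0("noise", seq_len(n_noise - 1)))
    }
    Xd <- NULL
    if (n_duplicates > 0) {
      src <- rep(seq_len(n_informative), length.out = n_duplicates)
      Xd <- vapply(src, function(s) {
        if (duplicate_r >= 1) Xi[, s]
        else {
          tau <- sqrt(1 / duplicate_r^2 - 1)
          Xi[, s] + stats::rnorm(n_rows, 0, tau)
        }
      }, numeric(n_rows))
      colnames(Xd) <- paste0("dup", seq_len(n_duplicates))
    }
    X <- cbind(Xi, Xn, Xd)
    roles <- c(rep("informative", n_informative), rep("noise", n_noise),
               rep("duplicate", n_duplicates))
    names(roles) <- colnames(X)
    list(X = X, y = y, roles = roles)
  })
}
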