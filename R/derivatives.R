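# Systematic substituent enumeration on quinone scaffolds with symmetry-aware
# deduplication.  Substitution sites are carbon-bound hydrogens only; the
# electron-withdrawing substituents of interest (-CN, -C#CMe) are shipped as
# defaults.

#' Default substituent set
#'
#' Monovalent fragments attached through their first atom: cyano (`C#N`) and
#' propynyl / methyl-capped alkynyl (`C#CC`).
#'
#' @return named list of substituent specs (`name`, `smiles`, parsed
#'   `fragment` graph, `attach` atom index).
#' @export
default_substituents <- function() {
  list(
    CN    = substituent_spec("CN", "C#N"),
    CCMe  = substituent_spec("CCMe", "C#CC")
  )
}

#' Define a monovalent substituent
#'
#' @param name short label used in manifests.
#' @param smiles fragment SMILES; the first atom is the attachment point and
#'   must have at least one hydrogen to give up for the new bond.
#' @return substituent spec list.
#' @export
substituent_spec <- function(name, smiles) {
  frag <- parse_smiles(smiles, name = name)
  if (frag$atoms$nH[1] < 1) {
    stop("substituent '", name, "' is not monovalent: first atom of '",
         smiles, "' has no hydrogen to replace")
  }
  list(name = name, smiles = smiles, fragment = frag, attach = 1L)
}

#' Symmetry-unique substitutable positions of a scaffold
#'
#' One representative atom index per symmetry class of carbon atoms carrying
#' at least one hydrogen.
#'
#' @param mol a [molgraph()].
#' @return integer vector of atom indices (possibly empty), one per class,
#'   each the lowest-index member of its class.
#' @export
substitutable_positions <- function(mol) {
  eligible <- which(mol$atoms$element == "C" & mol$atoms$nH >= 1)
  if (!length(eligible)) return(integer(0))
  sc <- symmetry_classes(mol)
  reps <- vapply(split(eligible, sc$class_id[eligible]), min, integer(1))
  unname(sort(reps))
}

# Attach a substituent fragment to `mol` at atom `pos` (consumes one H).
attach_substituent <- function(mol, pos, sub) {
  if (mol$atoms$nH[pos] < 1) stop("no hydrogen to substitute at atom ", pos)
  frag <- sub$fragment
  off <- n_atoms(mol)
  atoms <- rbind(mol$atoms, frag$atoms)
  fb <- frag$bonds
  if (nrow(fb)) { fb$i <- fb$i + off; fb$j <- fb$j + off }
  newbond <- data.frame(i = pos, j = off + sub$attach, order = 1L,
                        aromatic = FALSE)
  bonds <- rbind(mol$bonds, fb, newbond)
  atoms$nH[pos] <- atoms$nH[pos] - 1L
  atoms$nH[off + sub$attach] <- atoms$nH[off + sub$attach] - 1L
  molgraph(atoms, bonds, name = mol$name, validate = FALSE)
}

#' Enumerate substituted derivatives of quinone scaffolds
#'
#' Generates all distinct derivatives bearing up to `max_substitutions`
#' substituent groups, substituting carbon-bound hydrogens only.  Symmetry
#' classes restrict the search to unique positions and derivatives are
#' deduplicated globally (across scaffolds by default) by canonical form.
#'
#' @param scaffolds list of [molgraph()] scaffolds.
#' @param substituents list of substituent specs
#'   (default [default_substituents()]).
#' @param max_substitutions maximum number of substituent groups per
#'   derivative (default 1).
#' @param cross_scaffold_dedup emit a derivative reachable from two scaffolds
#'   only once (default `TRUE`).
#' @return a `derivative_set`: list with `molecules` (list of `molgraph`),
#'   and `manifest` data.frame (canonical, parent, n_subs, substituents),
#'   ordered by canonical form.
#' @export
enumerate_derivatives <- function(scaffolds,
                                  substituents = default_substituents(),
                                  max_substitutions = 1L,
                                  cross_scaffold_dedup = TRUE) {
  if (max_substitutions < 1L) stop("max_substitutions must be >= 1")
  for (s in substituents) {
    if (s$fragment$atoms$nH[s$attach] < 1) {
      stop("substituent '", s$name, "' is not monovalent")
    }
  }
  seen <- character(0)
  out_mol <- list(); out_parent <- character(0)
  out_nsub <- integer(0); out_subs <- character(0); out_canon <- character(0)
  n_dup <- 0L

  for (scf in scaffolds) {
    parent_canon <- canonical_form(scf)
    # breadth-first over substitution levels; per-scaffold dedup by canon
    level <- list(list(mol = scf, subs = character(0)))
    local_seen <- parent_canon
    for (k in seq_len(max_substitutions)) {
      nxt <- list()
      for (entry in level) {
        positions <- substitutable_positions(entry$mol)
        for (pos in positions) {
          for (s in substituents) {
            der <- attach_substituent(entry$mol, pos, s)
            cf <- canonical_form(der)
            if (cf %in% local_seen) next
            local_seen <- c(local_seen, cf)
            rec <- list(mol = der, subs = c(entry$subs, s$name), canon = cf)
            nxt[[length(nxt) + 1L]] <- rec
            if (cf %in% seen) { n_dup <- n_dup + 1L; next }
            seen <- c(seen, cf)
            out_mol[[length(out_mol) + 1L]] <- der
            out_parent <- c(out_parent, parent_canon)
            out_nsub <- c(out_nsub, k)
            out_subs <- c(out_subs,
                          paste(sort(rec$subs, method = "radix"), collapse = "+"))
            out_canon <- c(out_canon, cf)
          }
        }
      }
      level <- nxt
      if (!length(level)) break
    }
    if (!cross_scaffold_dedup) seen <- character(0)
  }

  ord <- order(out_canon, method = "radix")
  manifest <- data.frame(canonical = out_canon[ord],
                         parent = out_parent[ord],
                         n_subs = out_nsub[ord],
                         substituents = out_subs[ord],
                         stringsAsFactors = FALSE)
  structure(list(molecules = out_mol[ord], manifest = manifest,
                 n_deduplicated = n_dup),
            class = "derivative_set")
}

#' @export
print.derivative_set <- function(x, ...) {
  cat(sprintf("<derivative_set> %d derivatives from %d parent scaffold(s); %d cross-scaffold duplicates removed\n",
              nrow(x$manifest), length(unique(x$manifest$parent)),
              x$n_deduplicated))
  invisible(x)
}

#' Built-in quinone scaffold fixtures
#'
#' A small library of quinone backbones (benzoquinones, naphthoquinones,
#' anthraquinone and heteroaromatic congeners) bundled with the package for
#' the synthetic-data generator and for examples.
#'
#' @return list of [molgraph()] scaffolds.
#' @export
builtin_scaffolds <- function() {
  path <- system.file("extdata", "scaffolds.smi", package = "quinoscreen")
  if (!nzchar(path)) stop("bundled scaffold file not found")
  read_smi(path)$molecules
}
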