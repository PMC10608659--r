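# SMILES reader/writer for the organic subset used by the quinone pipeline.
# Supported: B C N O F P S Cl Br I Si (aromatic b c n o p s), branches, ring
# closures (including %nn), bond symbols - = # :, bracket atoms with H count
# and formal charge.  Stereo markers (/ \ @) are accepted and ignored: the
# pipeline is 2D/topological.  Aromaticity is taken from lowercase notation
# and additionally perceived on alternating kekule 6-rings.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "Si")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @return a [molgraph()] with aromaticity perceived and implicit hydrogen
#'   counts filled in.
#' @examples
#' mol <- parse_smiles("O=C1C=CC(=O)C=C1", name = "1,4-benzoquinone")
#' mol_formula(mol)
#' @export
parse_smiles <- function(smiles, name = "") {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    stop("SMILES must be a single non-empty string")
  }
  s <- trimws(smiles)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  el <- character(0); chg <- integer(0); hexp <- integer(0); arom <- logical(0)
  bi <- integer(0); bj <- integer(0); bord <- integer(0); barom <- logical(0)
  # ring bond bookkeeping: label -> c(atom, pending bond code)
  ring_open <- list()
  stack <- integer(0)     # branch stack of previous-atom indices
  prev <- 0L
  pending_bond <- NA_character_

  add_atom <- function(sym, aromatic, charge = 0L, hcount = NA_integer_) {
    el <<- c(el, sym); chg <<- c(chg, as.integer(charge))
    hexp <<- c(hexp, hcount); arom <<- c(arom, aromatic)
    length(el)
  }
  add_bond <- function(a, b, code) {
    if (a == 0L) stop("bond with no preceding atom")
    ord <- switch(ifelse(is.na(code), ".default", code),
                  "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                  "/" = 1L, "\\" = 1L, .default = 1L)
    ar <- identical(code, ":") ||
      (is.na(code) && arom[a] && arom[b])
    bi <<- c(bi, a); bj <<- c(bj, b); bord <<- c(bord, ord); barom <<- c(barom, ar)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch; i <- i + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") stop("disconnected SMILES (dot) not supported: ", s)
    if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure in: ", s)
        lab <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (prev == 0L) stop("ring closure before any atom in: ", s)
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- list(atom = prev, bond = pending_bond)
      } else {
        opened <- ring_open[[lab]]
        code <- if (!is.na(pending_bond)) pending_bond else opened$bond
        add_bond(opened$atom, prev, if (is.null(code)) NA_character_ else code)
        ring_open[[lab]] <- NULL
      }
      pending_bond <- NA_character_
      next
    }
    if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (!length(close)) stop("unclosed bracket atom in: ", s)
      close <- close[1]
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, s)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$hcount)
      if (prev > 0L) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
      i <- close + 1L
      next
    }
    # organic-subset atom, possibly two letters (Cl, Br, Si)
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br", "Si")) {
      idx <- add_atom(two, FALSE); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "F", "P", "S", "I")) {
      idx <- add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE); i <- i + 1L
    } else {
      stop("unrecognized SMILES token '", ch, "' in: ", s)
    }
    if (prev > 0L) add_bond(prev, idx, pending_bond)
    pending_bond <- NA_character_
    prev <- idx
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", s)
  open_labs <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_labs)) stop("unclosed ring bond(s) in: ", s)

  mol <- molgraph(
    atoms = data.frame(element = el, charge = chg, nH = 0L, aromatic = arom),
    bonds = data.frame(i = bi, j = bj, order = bord, aromatic = barom),
    name = name, validate = FALSE
  )
  mol <- .demote_nonring_aromatic(mol)
  mol <- .perceive_kekule_aromaticity(mol)
  mol <- .assign_hydrogens(mol, hexp)
  validate_molgraph(mol)
  mol
}

.parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(body,
    regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]?))?([+-][0-9]*|\\+\\+|--)?$",
            body))[[1]]
  if (!length(m)) stop("unparseable bracket atom [", body, "] in: ", smiles)
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  if (aromatic) sym <- toupper(sym)
  hcount <- if (nzchar(m[5])) {
    if (nzchar(m[6])) as.integer(m[6]) else 1L
  } else 0L
  charge <- 0L
  cstr <- m[7]
  if (nzchar(cstr)) {
    if (cstr %in% c("+", "-")) charge <- if (cstr == "+") 1L else -1L
    else if (cstr %in% c("++", "--")) charge <- if (cstr == "++") 2L else -2L
    else charge <- as.integer(paste0(substr(cstr, 1, 1), substring(cstr, 2)))
  }
  list(element = sym, aromatic = aromatic, charge = charge, hcount = hcount)
}

# A bond flagged aromatic that is not in any cycle (e.g. biphenyl written in
# lowercase without an explicit single bond) is demoted to a plain single bond.
.demote_nonring_aromatic <- function(mol) {
  if (!n_bonds(mol)) return(mol)
  ring <- bond_in_ring(mol)
  fix <- mol$bonds$aromatic & !ring
  if (any(fix)) {
    mol$bonds$aromatic[fix] <- FALSE
    mol$bonds$order[fix] <- 1L
  }
  mol
}

# TRUE for each bond that lies on a cycle (removal keeps endpoints connected).
bond_in_ring <- function(mol) {
  nb <- n_bonds(mol)
  out <- logical(nb)
  if (!nb) return(out)
  for (k in seq_len(nb)) {
    sub <- mol
    sub$bonds <- mol$bonds[-k, , drop = FALSE]
    out[k] <- .connected_pair(sub, mol$bonds$i[k], mol$bonds$j[k])
  }
  out
}

.connected_pair <- function(mol, a, b) {
  adj <- adjacency_list(mol)
  seen <- logical(n_atoms(mol))
  queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v == b) return(TRUE)
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  seen[b]
}

# Mark alternating kekule 6-rings (single/double strictly alternating around
# the cycle) as aromatic.  This covers benzene-like carbocycles and pyridine
# written in uppercase; quinoid rings do not alternate and stay non-aromatic.
.perceive_kekule_aromaticity <- function(mol) {
  cycles <- .find_cycles(mol, max_len = 6L)
  if (!length(cycles)) return(mol)
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (cyc in cycles) {
    if (length(cyc) != 6L) next
    ords <- integer(6)
    idxs <- integer(6)
    ok <- TRUE
    for (t in seq_len(6)) {
      a <- cyc[t]; b <- cyc[if (t == 6L) 1L else t + 1L]
      kk <- match(paste(min(a, b), max(a, b)), bkey)
      if (is.na(kk)) { ok <- FALSE; break }
      idxs[t] <- kk
      ords[t] <- if (mol$bonds$aromatic[kk]) 99L else mol$bonds$order[kk]
    }
    if (!ok) next
    if (any(ords == 99L)) next                   # already aromatic
    alt1 <- all(ords == rep(c(1L, 2L), 3)) || all(ords == rep(c(2L, 1L), 3))
    if (alt1) {
      mol$bonds$aromatic[idxs] <- TRUE
      mol$bonds$order[idxs] <- 1L
      mol$atoms$aromatic[cyc] <- TRUE
    }
  }
  mol
}

# All simple cycles up to max_len, each reported once as an atom sequence.
.find_cycles <- function(mol, max_len = 6L) {
  adj <- adjacency_list(mol)
  n <- n_atoms(mol)
  found <- list()
  seen_keys <- character(0)
  path <- integer(0)
  walk <- function(start, v) {
    path <<- c(path, v)
    if (length(path) <= max_len) {
      for (w in adj[[v]]) {
        if (w == start && length(path) >= 3L) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen_keys)) {
            seen_keys <<- c(seen_keys, key)
            found[[length(found) + 1L]] <<- path
          }
        } else if (!(w %in% path) && w > start) {
          walk(start, w)
        }
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) walk(s, s)
  # keep only chordless traversal orders of genuine cycles: verify consecutive
  # adjacency (walk construction already guarantees it)
  found
}

# Fill attached-H counts.  hexp carries explicit bracket H counts (NA for
# organic-subset atoms, which get the default-valence rule).
.assign_hydrogens <- function(mol, hexp) {
  bos <- bond_order_sum(mol)
  deg <- atom_degree(mol)
  info <- .element_row(mol$atoms$element)
  nH <- integer(n_atoms(mol))
  for (a in seq_len(n_atoms(mol))) {
    if (!is.na(hexp[a])) { nH[a] <- hexp[a]; next }
    if (mol$atoms$aromatic[a]) {
      nH[a] <- max(0L, info$valence[a] - as.integer(floor(bos[a])))
    } else {
      val_eff <- info$valence[a] + mol$atoms$charge[a]
      nH[a] <- max(0L, as.integer(val_eff - bos[a]))
    }
  }
  mol$atoms$nH <- nH
  mol
}

#' Read a one-SMILES-per-line file
#'
#' Lines hold a SMILES string with an optional whitespace-separated name.
#' Records that fail to parse, and (by default) charged species, are rejected
#' with a diagnostic while the reader continues.
#'
#' @param path path to a `.smi` file.
#' @param reject_charged drop molecules carrying a non-zero formal charge
#'   (default `TRUE`).
#' @return list with `molecules` (list of `molgraph`) and `rejected`
#'   (data.frame of line, smiles, reason).
#' @export
read_smi <- function(path, reject_charged = TRUE) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  rej <- data.frame(line = integer(), smiles = character(),
                    reason = character(), stringsAsFactors = FALSE)
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    smi <- parts[1]
    nm <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
    mol <- tryCatch(parse_smiles(smi, name = nm), error = function(e) e)
    if (inherits(mol, "error")) {
      rej <- rbind(rej, data.frame(line = k, smiles = smi,
                                   reason = conditionMessage(mol)))
      next
    }
    if (reject_charged && any(mol$atoms$charge != 0)) {
      rej <- rbind(rej, data.frame(line = k, smiles = smi,
                                   reason = "charged species rejected"))
      next
    }
    mols[[length(mols) + 1L]] <- mol
  }
  list(molecules = mols, rejected = rej)
}

# Write a SMILES string for `mol` visiting atoms in the order implied by
# `rank` (lower rank printed first; neighbour order by increasing rank).
write_smiles <- function(mol, rank = seq_len(n_atoms(mol))) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  bkey <- if (n_bonds(mol)) {
    paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  } else character(0)
  bond_of <- function(a, b) match(paste(min(a, b), max(a, b)), bkey)
  info <- .element_row(mol$atoms$element)

  visited <- logical(n)
  ring_digit <- 0L
  ring_label <- list()     # bond index -> digit
  # pre-pass: find ring-closure bonds via DFS spanning tree
  tree_edge <- matrix(FALSE, n, n)
  order_visit <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    order_visit <<- c(order_visit, v)
    nbs <- adj[[v]][order(rank[adj[[v]]])]
    for (w in nbs) {
      if (!visited[w]) {
        tree_edge[v, w] <<- TRUE
        dfs1(w)
      }
    }
  }
  root <- which.min(rank)
  dfs1(root)
  if (!all(visited)) stop("cannot write SMILES of a disconnected graph")
  # ring-closure bonds (non-tree edges) indexed per atom; digits are assigned
  # lazily in traversal order so the emitted string is canonical
  atom_closures <- vector("list", n)
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
      if (!tree_edge[a, b] && !tree_edge[b, a]) {
        atom_closures[[a]] <- c(atom_closures[[a]], k)
        atom_closures[[b]] <- c(atom_closures[[b]], k)
      }
    }
  }
  digit_of <- rep(NA_integer_, max(1L, n_bonds(mol)))

  atom_token <- function(a) {
    sym <- mol$atoms$element[a]
    bos <- bond_order_sum(mol)[a]
    implied <- if (mol$atoms$aromatic[a]) {
      max(0L, info$valence[a] - as.integer(floor(bos)))
    } else {
      max(0L, as.integer(info$valence[a] + mol$atoms$charge[a] - bos))
    }
    bare_ok <- sym %in% .ORGANIC_SUBSET && mol$atoms$charge[a] == 0L &&
      implied == mol$atoms$nH[a]
    disp <- if (mol$atoms$aromatic[a]) tolower(sym) else sym
    if (bare_ok) return(disp)
    h <- mol$atoms$nH[a]
    chg <- mol$atoms$charge[a]
    paste0("[", disp,
           if (h == 1) "H" else if (h > 1) paste0("H", h) else "",
           if (chg > 0) paste0("+", if (chg > 1) chg else "") else "",
           if (chg < 0) paste0("-", if (chg < -1) -chg else "") else "",
           "]")
  }

  visited2 <- logical(n)
  emit <- function(v, incoming_sym) {
    visited2[v] <<- TRUE
    ctoks <- ""
    cl <- atom_closures[[v]]
    if (length(cl)) {
      others <- ifelse(mol$bonds$i[cl] == v, mol$bonds$j[cl], mol$bonds$i[cl])
      cl <- cl[order(rank[others])]
      for (k in cl) {
        if (is.na(digit_of[k])) {
          ring_digit <<- ring_digit + 1L
          digit_of[k] <<- ring_digit
        }
        d <- digit_of[k]
        ctoks <- paste0(ctoks, .bond_sym(mol, k),
                        if (d < 10) d else paste0("%", d))
      }
    }
    out <- paste0(incoming_sym, atom_token(v), ctoks)
    kids <- adj[[v]][tree_edge[v, adj[[v]]]]
    kids <- kids[order(rank[kids])]
    if (length(kids)) {
      for (t in seq_along(kids)) {
        w <- kids[t]
        bs <- .bond_sym(mol, bond_of(v, w))
        sub <- emit(w, bs)
        if (t < length(kids)) out <- paste0(out, "(", sub, ")")
        else out <- paste0(out, sub)
      }
    }
    out
  }
  emit(root, "")
}

# Printable bond symbol for bond k ("" for single/aromatic defaults, with an
# explicit "-" for single bonds linking two aromatic atoms).
.bond_sym <- function(mol, k) {
  if (is.na(k)) return("")
  if (mol$bonds$aromatic[k]) return("")
  ord <- mol$bonds$order[k]
  both_ar <- mol$atoms$aromatic[mol$bonds$i[k]] && mol$atoms$aromatic[mol$bonds$j[k]]
  if (ord == 1L) return(if (both_ar) "-" else "")
  if (ord == 2L) return("=")
  "#"
}
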