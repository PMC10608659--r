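test_that("intrinsic states match the defining formula on hand cases", {
  eth <- parse_smiles("CC")
  st <- intrinsic_states(eth)
  expect_equal(st$I, c(2, 2), tolerance = 1e-12)   # ((2/2)^2*1+1)/1
  fm <- parse_smiles("CF")
  stf <- intrinsic_states(fm)
  f_idx <- which(fm$atoms$element == "F")
  expect_equal(stf$I[f_idx], 8, tolerance = 1e-12) # (1*7+1)/1
  # all atoms equivalent -> no intrinsic-state differences
  d <- compute_descriptors(eth)$values
  expect_equal(unname(d["MAXDN2"]), 0)
  expect_equal(unname(d["MAXDP2"]), 0)
  expect_error(intrinsic_states(parse_smiles("C")), "single")
})

test_that("E-state perturbations are pairwise antisymmetric", {
  for (mol in fixture_mols()) {
    if (nrow(mol$atoms) < 2) next
    st <- intrinsic_states(mol)
    expect_lt(abs(sum(st$S - st$I)), 1e-10)
  }
})

test_that("atom-type counts match direct pattern matching", {
  bq <- parse_smiles("O=C1C=CC(=O)C=C1")
  d <- compute_descriptors(bq)$values
  expect_equal(unname(d["ndssC"]), 2)              # two carbonyl =C<
  expect_equal(unname(d["nHother"]), 4)            # four =CH- hydrogens
  bz <- parse_smiles("c1ccccc1")
  dz <- compute_descriptors(bz)$values
  expect_equal(unname(dz["naasC"]), 0)             # aaC- needs a substituent
  expect_equal(unname(dz["nHother"]), 6)           # six aaCH hydrogens
  tol <- parse_smiles("Cc1ccccc1")
  expect_equal(unname(compute_descriptors(tol)$values["naasC"]), 1)
  an <- parse_smiles("CC#N")
  expect_equal(unname(compute_descriptors(an)$values["ntN"]), 1)
})

test_that("topological descriptors match their definitions", {
  eth <- parse_smiles("CC")
  d <- compute_descriptors(eth)$values
  expect_equal(unname(d["ECCEN"]), 2)
  expect_equal(unname(d["topoDiameter"]), 1)
  pr <- parse_smiles("CCC")
  dp <- compute_descriptors(pr)$values
  expect_equal(unname(dp["ECCEN"]), 6)             # 2*1 + 1*2 + 2*1
  bq <- parse_smiles("O=C1C=CC(=O)C=C1")
  db <- compute_descriptors(bq)$values
  expect_equal(unname(db["nRing"]), 1)
  expect_equal(unname(db["nBondsD2"]), 4)          # 2 C=O + 2 ring C=C
})

test_that("ECCEN and diameter agree with an igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (mol in fixture_mols()) {
    if (nrow(mol$bonds) == 0) next
    g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                     directed = FALSE)
    D <- igraph::distances(g)
    ecc <- apply(D, 1, max)
    deg <- igraph::degree(g)
    d <- compute_descriptors(mol)$values
    expect_equal(unname(d["ECCEN"]), sum(ecc * deg))
    expect_equal(unname(d["topoDiameter"]), max(ecc))
  }
})

test_that("van der Waals volumes follow the additive bond/ring-corrected sum", {
  expect_equal(vabc_volume(parse_smiles("C")), 25.86, tolerance = 1e-6)
  # one aromatic ring correction for benzene
  bz <- parse_smiles("c1ccccc1")
  expect_equal(vabc_volume(bz), 6 * 20.58 + 6 * 7.24 - 5.92 * 12 - 14.7,
               tolerance = 1e-6)
  # adding -CN strictly increases the volume
  bq <- parse_smiles("O=C1C=CC(=O)C=C1")
  der <- enumerate_derivatives(list(bq), default_substituents()["CN"])
  expect_gt(vabc_volume(der$molecules[[1]]), vabc_volume(bq))
})

test_that("Burden-matrix extremes behave like a symmetric spectrum", {
  for (mol in fixture_mols()) {
    b <- bcut_extremes(mol)
    expect_lte(b[["BCUTc.1l"]], b[["BCUTc.1h"]])
  }
  # ethane with zeroed charges: pure 2x2 connectivity matrix, terminal bond
  # weight 0.1 + 0.01, eigenvalues +/- 0.11
  eth <- parse_smiles("CC")
  b <- bcut_extremes(eth, charges = c(0, 0))
  expect_equal(unname(b), c(-0.11, 0.11), tolerance = 1e-12)
})

test_that("Hueckel pseudo-LUMO reproduces analytic pi systems", {
  alpha <- -6.6; beta <- -2.7
  expect_equal(pseudo_lumo(parse_smiles("C=C")), alpha - beta,
               tolerance = 1e-9)
  phi <- (sqrt(5) - 1) / 2                         # 0.618...
  expect_equal(pseudo_lumo(parse_smiles("C=CC=C")), alpha - phi * beta,
               tolerance = 1e-3)
  expect_true(is.na(pseudo_lumo(parse_smiles("CCC"))))
  # electron-withdrawing -CN lowers the pseudo-LUMO of benzoquinone
  bq <- parse_smiles("O=C1C=CC(=O)C=C1")
  bqcn <- parse_smiles("O=C1C=CC(=O)C(C#N)=C1")
  expect_lt(pseudo_lumo(bqcn), pseudo_lumo(bq))
})

test_that("all descriptors are invariant under atom relabeling", {
  set.seed(7)
  for (mol in fixture_mols()[c("benzoquinone", "menadione", "acetonitrile")]) {
    ref <- compute_descriptors(mol)$values
    for (t in 1:10) {
      perm <- sample(nrow(mol$atoms))
      got <- compute_descriptors(quinoscreen:::permute_atoms(mol, perm))$values
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("descriptor table has fixed shape, order and missing flags", {
  empty <- compute_descriptor_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(descriptor_names() %in% colnames(empty)))

  bq <- parse_smiles("O=C1C=CC(=O)C=C1")
  ders <- enumerate_derivatives(list(bq))
  tab <- compute_descriptor_table(c(list(bq), ders$molecules))
  expect_equal(nrow(tab), 3)
  expect_identical(colnames(tab)[2:33], descriptor_names())
  # MW strictly increases with substitution
  expect_true(all(tab$MW[2:3] > tab$MW[1]))
  # duplicated molecule gives identical rows
  tab2 <- compute_descriptor_table(list(bq, bq))
  expect_equal(tab2[1, ], tab2[2, ], ignore_attr = TRUE)
  # a saturated molecule flags LUMO as missing
  tabs <- compute_descriptor_table(list(parse_smiles("CCC")))
  expect_true(tabs$na_LUMO)
  expect_equal(tabs$LUMO, 0)
})
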