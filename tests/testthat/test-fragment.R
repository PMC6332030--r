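tok <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(prefix = m[, 1], element = m[, 2], count = as.integer(m[, 3]),
             stringsAsFactors = FALSE)
}

test_that("neighbour terms render canonically", {
  expect_equal(neighborTerm(tok("", "H", 2, "", "C", 1, "", "N", 1), charge = 1L),
               "H2CN(+)")
  expect_equal(neighborTerm(tok("", "C", 1, "", "O", 1, "=", "O", 1)), "CO=O")
  expect_equal(neighborTerm(tok("", "H", 2, "", "C", 1), pi = 1L), "H2C(pi)")
  # ordering: element rank major, bond type minor; iodine rendered J
  expect_equal(neighborTerm(tok(":", "C", 2, "", "C", 1)), "C:C2")
  expect_equal(neighborTerm(tok("", "I", 1, "", "H", 2, "", "C", 1)), "H2CJ")
  expect_equal(neighborTerm(tok("#", "C", 1, "", "H", 1)), "H#C")
  # token aggregation across duplicate entries
  expect_equal(neighborTerm(tok("=", "O", 1, "", "C", 2, "=", "O", 1)), "C2=O2")
  expect_error(neighborTerm(tok("", "Xe", 1)), "unknown element")
  expect_error(neighborTerm(tok("", "C", 0)), "count")
})

test_that("canonicalization is a fixed point and parse inverts render", {
  for (term in c("H3C", "H2CN(+)", "CO=O(-)", "H2C(pi)", "C2N(2pi)",
                 "HCN(+)(2pi)", ":C2O(-)", "=N2(-)", "H#C", "=C=O",
                 "O2=O2", "C:C2", ":CN:N", "H2CJ", "SiCl3", "N2O=O")) {
    p <- parseNeighborTerm(term)
    expect_identical(neighborTerm(p$tokens, p$charge, p$pi), term, info = term)
  }
  expect_error(parseNeighborTerm("C%"), "unparsable")
})

test_that("every packaged table key is a canonical fragmenter string", {
  for (id in availableDescriptors()) {
    e <- tableEntries(packagedTable(id))
    grp <- e[grepl("|", e$key, fixed = TRUE), ]
    for (k in seq_len(nrow(grp))) {
      p <- parseNeighborTerm(grp$neighbors[k])
      expect_identical(neighborTerm(p$tokens, p$charge, p$pi),
                       grp$neighbors[k],
                       info = paste(id, grp$key[k]))
    }
  }
})

test_that("group keys match the table vocabulary", {
  me <- mol("CO", "methanol")
  o <- which(atoms(me)$element == "O")
  expect_equal(groupKey(me, o), c("O", "HC"))

  ph <- mol("Oc1ccccc1", "phenol")
  o <- which(atoms(ph)$element == "O")
  expect_equal(groupKey(ph, o), c("O", "HC(pi)"))

  azo <- mol("c1ccccc1N=Nc1ccccc1", "azobenzene")
  n <- which(atoms(azo)$element == "N")[1]
  expect_equal(groupKey(azo, n), c("N sp2", "C=N"))

  # atoms with a single neighbour are not backbones
  h <- which(atoms(me)$element == "H")[1]
  expect_null(groupKey(me, h))
})

test_that("fragmentation reproduces hand-derived profiles", {
  g <- gcounts(mol("C(C(=O)[O-])[NH3+]", "glycine"))
  expect_equal(g[order(names(g))],
               c(`C sp2|CO=O(-)` = 1, `C sp3|H2CN(+)` = 1, `N(+) sp3|H3C` = 1))

  e <- gcounts(mol(strrep("C", 20), "eicosane"))
  expect_equal(e[order(names(e))], c(`C sp3|H2C2` = 18, `C sp3|H3C` = 2))

  # methane: the single backbone candidate is emitted (all-H neighbourhood);
  # no table carries the key, so the applicability gate rejects it downstream
  m <- gcounts(mol("C", "methane"))
  expect_equal(m, c(`C sp3|H4` = 1))

  # amide nitrogen: sp3 label with pi suffix from the carbonyl neighbour
  ac <- gcounts(mol("CC(=O)NC", "N-methylacetamide"))
  expect_true("N sp3|HC2(pi)" %in% names(ac))

  # every backbone atom contributes exactly one group count
  for (smi in c("CCO", "Oc1ccccc1", "CC(=O)NC", "C(C(=O)[O-])[NH3+]")) {
    m <- mol(smi)
    nBackbone <- sum(vapply(seq_len(nrow(atoms(m))), function(i)
      !is.null(groupKey(m, i)), logical(1)))
    expect_equal(sum(gcounts(m)), nBackbone, info = smi)
  }
})

test_that("fragmentation is invariant to input form and atom order", {
  a <- gcounts(mol("OCC", "ethanol-a"))
  b <- gcounts(mol("CCO", "ethanol-b"))
  expect_equal(a[order(names(a))], b[order(names(b))])

  # same structure via SDF text instead of SMILES
  ph <- mol("Oc1ccccc1", "phenol")
  path <- writeSDFile(list(GroupAdditivity:::.molblockFromMolecule(ph)))
  ph2 <- readSDF(path)[[1]]
  p1 <- gcounts(ph); p2 <- gcounts(ph2)
  expect_equal(p1[order(names(p1))], p2[order(names(p2))])
})

test_that("pi suffixes count conjugated neighbours of N sp3 / O / S2 only", {
  # aniline NH2: one aromatic neighbour
  an <- gcounts(mol("Nc1ccccc1", "aniline"))
  expect_true("N sp3|H2C(pi)" %in% names(an))
  # diphenylamine: two
  dpa <- gcounts(mol("c1ccccc1Nc1ccccc1"))
  expect_true("N sp3|HC2(2pi)" %in% names(dpa))
  # ester ether-oxygen: one conjugated (carbonyl) neighbour
  es <- gcounts(mol("CC(=O)OC", "methyl acetate"))
  expect_true("O|C2(pi)" %in% names(es))
  # furan oxygen: both kekule neighbours conjugated
  fu <- gcounts(mol("c1ccoc1", "furan"))
  expect_true("O|C2(2pi)" %in% names(fu))
  # charged N gets no pi suffix
  gly <- gcounts(mol("C(C(=O)[O-])[NH3+]"))
  expect_true("N(+) sp3|H3C" %in% names(gly))
})
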