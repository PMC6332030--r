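test_that("SMILES parsing expands hydrogens and perceives charges", {
  m <- mol("CO")
  expect_equal(nrow(atoms(m)), 6L)  # CH3OH with explicit H
  expect_equal(sum(atoms(m)$element == "H"), 4L)

  g <- mol("C(=O)([O-])C[NH3+]", "glycine")
  expect_equal(netCharge(g), 0L)
  expect_equal(sum(atoms(g)$charge != 0), 2L)

  p <- mol("c1ccccc1O")
  expect_equal(sum(atoms(p)$aromatic), 6L)
  expect_true(all(atoms(p)$element[atoms(p)$aromatic] == "C"))

  expect_error(parseSmiles("C1CC"), "SMILES parse error")
})

test_that("benzenoid aromaticity model keeps five-membered heteroaromatics kekule", {
  # pyridine: aromatic N; furan/thiophene/pyrrole: no aromatic atoms
  expect_equal(sum(atoms(mol("c1ccncc1"))$aromatic), 6L)
  expect_equal(sum(atoms(mol("c1ccoc1"))$aromatic), 0L)
  expect_equal(sum(atoms(mol("c1ccsc1"))$aromatic), 0L)
  expect_equal(sum(atoms(mol("c1cc[nH]c1"))$aromatic), 0L)
  # fused: naphthalene fully aromatic, 2-pyridone lactam ring is not
  expect_equal(sum(atoms(mol("c1ccc2ccccc2c1"))$aromatic), 10L)
  expect_equal(sum(atoms(mol("O=c1cccc[nH]1"))$aromatic), 0L)
  # but the lactim tautomer is
  expect_equal(sum(atoms(mol("Oc1ccccn1"))$aromatic), 6L)
})

test_that("MOL/SDF reading: records, properties, rejections, empty file", {
  path <- writeSDFile(list(methaneMolblock()))
  ms <- readSDF(path)
  expect_length(ms, 1L)
  expect_equal(nrow(atoms(ms[[1]])), 5L)
  expect_equal(nrow(bonds(ms[[1]])), 4L)
  expect_true(all(bonds(ms[[1]])$order == 1L))

  # data field with a recognized tag populates properties
  phenol <- mol("Oc1ccccc1", "phenol")
  path2 <- writeSDFile(list(GroupAdditivity:::.molblockFromMolecule(phenol)),
                       fields = list(list(LOGP_EXP = 1.46)))
  ms2 <- readSDF(path2)
  expect_equal(unname(properties(ms2[[1]])["logP"]), 1.46)

  # empty file: empty list, no error
  empty <- tempfile(fileext = ".sdf"); writeLines(character(), empty)
  expect_length(readSDF(empty), 0L)

  # a record with an unsupported element is rejected with its entry index
  ferrocene_ish <- sub(" C  ", " Fe ", methaneMolblock())
  path3 <- writeSDFile(list(methaneMolblock(), ferrocene_ish))
  expect_warning(ms3 <- readSDF(path3), "rejected")
  expect_length(ms3, 1L)
  errs <- attr(ms3, "errors")
  expect_equal(errs$index, 2L)
  expect_match(errs$message, "element")
})

test_that("molecular formula counts explicit hydrogens", {
  expect_equal(molecularFormula(mol("CC(=O)C")), c(C = 3L, H = 6L, O = 1L))
  expect_equal(molecularFormula(mol("Oc1ccc(cc1)N=Nc1ccccc1")),
               c(C = 12L, H = 10L, N = 2L, O = 1L))
  trip <- mol("CCCCCCCCCCCCCCCC(=O)OCC(OC(=O)CCCCCCCCCCCCCCC)COC(=O)CCCCCCCCCCCCCCC")
  expect_equal(molecularFormula(trip), c(C = 51L, H = 98L, O = 6L))
})

test_that("backbone labels follow the hybridization/valence/charge rules", {
  nb <- mol("O=[N+]([O-])c1ccccc1", "nitrobenzene")
  nIdx <- which(atoms(nb)$element == "N")
  expect_equal(backboneLabel(nb, nIdx), "N(+) sp2")

  sa <- mol("CS(=O)(=O)NC", "sulfonamide-like")
  sIdx <- which(atoms(sa)$element == "S")
  expect_equal(backboneLabel(sa, sIdx), "S4")

  al <- mol("C=C=C", "allene")
  center <- which(vapply(seq_len(nrow(atoms(al))), function(i) {
    b <- bonds(al); sum((b$i == i | b$j == i) & b$order == 2L) == 2L
  }, logical(1)))
  expect_equal(backboneLabel(al, center), "C sp")

  # thioether vs sulfone; phosphine vs phosphate
  expect_equal(backboneLabel(mol("CSC"), 2), "S2")
  p3 <- mol("CP(C)C"); expect_equal(backboneLabel(p3, which(atoms(p3)$element == "P")), "P3")
  p4 <- mol("COP(=O)(OC)OC")
  expect_equal(backboneLabel(p4, which(atoms(p4)$element == "P")), "P4")

  expect_error(backboneLabel(mol("CO"), which(atoms(mol("CO"))$element == "H")[1]),
               "cannot be a backbone")
})

test_that("parse -> write -> parse round-trips to an isomorphic graph", {
  for (smi in c("CCO", "c1ccccc1O", "C(C(=O)[O-])[NH3+]", "CC(=O)Oc1ccccc1C(=O)O",
                "C1CC1", "CSC", "O=[N+]([O-])c1ccccc1")) {
    m1 <- mol(smi)
    m2 <- parseSmiles(asSmiles(m1))
    expect_equal(molecularFormula(m2), molecularFormula(m1), info = smi)
    expect_equal(gcounts(m2), gcounts(m1), info = smi)
  }
})
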