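test_that("pure-hydrocarbon corrections count all carbons, mutually exclusively", {
  expect_equal(detectSpecialGroups(mol(strrep("C", 20)), c("Alkane", "UnsatHC")),
               c(Alkane = 20, UnsatHC = 0))
  expect_equal(detectSpecialGroups(mol("c1ccccc1"), c("Alkane", "UnsatHC")),
               c(Alkane = 0, UnsatHC = 6))
  expect_equal(detectSpecialGroups(mol("Cc1ccccc1"), c("Alkane", "UnsatHC")),
               c(Alkane = 0, UnsatHC = 7))
  expect_equal(detectSpecialGroups(mol("C#CC"), c("Alkane", "UnsatHC")),
               c(Alkane = 0, UnsatHC = 3))
  # heteroatom-containing molecules get neither
  expect_equal(detectSpecialGroups(mol("CCO"), c("Alkane", "UnsatHC")),
               c(Alkane = 0, UnsatHC = 0))
})

test_that("ring-strain angles are binned from 3D geometry, ring-internal only", {
  cp <- mol("C1CC1", embed3d = TRUE)
  a <- detectSpecialGroups(cp, c("Angle60", "Angle90", "Angle102"))
  expect_equal(unname(a["Angle60"]), 3)
  cb <- mol("C1CCC1", embed3d = TRUE)
  a4 <- detectSpecialGroups(cb, c("Angle60", "Angle90", "Angle102"))
  expect_equal(unname(a4["Angle90"]), 4)
  expect_equal(unname(a4["Angle60"]), 0)
  # benzene angles (120 deg) fall outside all strain bins
  bz <- mol("c1ccccc1", embed3d = TRUE)
  expect_true(all(detectSpecialGroups(bz, c("Angle60", "Angle90", "Angle102")) == 0))
})

test_that("geometry detectors refuse molecules without coordinates", {
  expect_error(detectSpecialGroups(mol("C1CC1"), "Angle60"), "3D coordinates")
  expect_error(detectSpecialGroups(mol("CCO"), "HH_lt2"), "3D coordinates")
  # composition detectors are fine without geometry
  expect_silent(detectSpecialGroups(mol("CCO"), c("Alkane", "UnsatHC", "XCH2n")))
})

test_that("H-H contacts exclude geminal/vicinal pairs and count each pair once", {
  et <- mol("CC", embed3d = TRUE)  # only geminal/vicinal H-H: nothing counted
  hh <- detectSpecialGroups(et, c("HH_lt2", "HH_2to2.3"))
  expect_true(all(hh == 0))
  # a congested molecule has some contacts in the 2-2.3 window
  val <- mol("CC(C)C(C(=O)[O-])[NH3+]", embed3d = TRUE)
  hhv <- detectSpecialGroups(val, c("HH_lt2", "HH_2to2.3"))
  expect_true(all(hhv >= 0))
  expect_true(all(hhv == round(hhv)))
})

test_that("intramolecular H-bridges: neutral donors/acceptors in 5-7 pseudo-rings", {
  sal <- mol("O=Cc1ccccc1O", "salicylaldehyde", embed3d = TRUE)
  expect_equal(unname(detectSpecialGroups(sal, "HBridge")["HBridge"]), 1)
  # para isomer cannot close a small pseudo-ring
  phb <- mol("O=Cc1ccc(O)cc1", embed3d = TRUE)
  expect_equal(unname(detectSpecialGroups(phb, "HBridge")["HBridge"]), 0)
  # charged contacts (zwitterion salt bridge) are not hydrogen bridges
  gly <- mol("C(C(=O)[O-])[NH3+]", embed3d = TRUE)
  expect_equal(unname(detectSpecialGroups(gly, "HBridge")["HBridge"]), 0)
})

test_that("X(CH2)n counts chains per policy", {
  cfg <- gaDefaultConfig()
  hex <- mol(paste0("OC", strrep("C", 15)), "1-hexadecanol")
  # default: only chains attached to an aromatic ring qualify
  expect_equal(unname(detectSpecialGroups(hex, "XCH2n", cfg)["XCH2n"]), 0)
  cfg$specials$xch2n_policy <- "unrestricted"
  expect_equal(unname(detectSpecialGroups(hex, "XCH2n", cfg)["XCH2n"]), 15)
  # aromatic-attached chain with hydroxyl end group
  ppol <- mol("OCCCc1ccccc1", "3-phenyl-1-propanol")
  expect_equal(unname(detectSpecialGroups(ppol, "XCH2n")["XCH2n"]), 3)
  cfgN1 <- gaDefaultConfig(); cfgN1$specials$xch2n_count <- "n-1"
  expect_equal(unname(detectSpecialGroups(ppol, "XCH2n", cfgN1)["XCH2n"]), 2)
  # single CH2 (n = 1) never qualifies
  bn <- mol("OCc1ccccc1", "benzyl alcohol")
  expect_equal(unname(detectSpecialGroups(bn, "XCH2n")["XCH2n"]), 0)
})

test_that("eligibility filter: charge, strong acids, element scope", {
  expect_true(eligibilityFilter(mol("C(C(=O)[O-])[NH3+]"), "logP")$pass)
  acetate <- mol("CC(=O)[O-]")
  res <- eligibilityFilter(acetate, "logP")
  expect_false(res$pass)
  expect_match(res$reason, "net charge")
  bsa <- mol("OS(=O)(=O)c1ccccc1", "benzenesulfonic acid")
  expect_false(eligibilityFilter(bsa, "logP")$pass)
  # strong-acid rule only applies to the configured descriptors
  expect_true(eligibilityFilter(bsa, "heat_of_combustion")$pass)
  # unsupported element (constructed directly; the parsers reject it earlier)
  fake <- new("Molecule", name = "fake",
              atoms = data.frame(element = c("Fe", "O", "O"),
                                 charge = 0L, aromatic = FALSE,
                                 x = 0, y = 0, z = 0),
              bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L), order = 1L,
                                 aromatic = FALSE),
              rings = list(), properties = setNames(numeric(), character()),
              is3d = FALSE)
  res <- eligibilityFilter(fake, "heat_of_combustion")
  expect_false(res$pass)
  expect_match(res$reason, "Fe")
})
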