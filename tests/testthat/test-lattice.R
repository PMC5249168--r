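test_that("symmetry expansion produces the expected copy counts", {
  mc <- generateMiniCrystal(miniCrystalSpec(nResidues = 6, gap = 10,
                                            spaceGroup = "P1"))
  nb1 <- expandNeighbors(mc$lattice, shell = 1)
  expect_length(nb1, 26)  # 3^3 - 1
  expect_length(expandNeighbors(mc$lattice, shell = 0), 0)
  natoms <- nrow(atoms(mc$lattice))
  expect_true(all(vapply(nb1, function(cp) nrow(cp$atoms), integer(1)) ==
                    natoms))
  mc21 <- generateMiniCrystal(miniCrystalSpec(nResidues = 6, gap = 10,
                                              spaceGroup = "P21"))
  expect_length(expandNeighbors(mc21$lattice, shell = 0), 1)
  expect_length(expandNeighbors(mc21$lattice, shell = 1), 2 * 27 - 1)
  expect_error(spaceGroupOperators("X9"), "space group")
})

test_that("contact flags follow the construction truth and the cutoff", {
  near <- generateMiniCrystal(miniCrystalSpec(nResidues = 8, gap = 3.5))
  got <- detectContacts(near$lattice, cutoff = 4.0)
  expect_identical(got$contacting, near$truth$contacting)
  expect_true(got$contacting[1] && got$contacting[8])
  expect_false(any(got$contacting[2:7]))

  far <- generateMiniCrystal(miniCrystalSpec(nResidues = 8, gap = 4.5))
  expect_false(any(detectContacts(far$lattice, cutoff = 4.0)$contacting))
  expect_false(any(generateMiniCrystal(
    miniCrystalSpec(nResidues = 8, gap = 10))$truth$contacting))

  # "within 4 A" is boundary-inclusive
  exact <- generateMiniCrystal(miniCrystalSpec(nResidues = 8, gap = 4.0))
  expect_true(any(detectContacts(exact$lattice, cutoff = 4.0)$contacting))
})

test_that("detectContacts equals the brute-force all-pairs oracle", {
  for (sg in c("P1", "P21")) {
    for (gap in c(3.0, 3.9, 5.5)) {
      mc <- generateMiniCrystal(miniCrystalSpec(nResidues = 12, gap = gap,
                                                spaceGroup = sg))
      expect_lte(nrow(atoms(mc$lattice)), 500)
      got <- detectContacts(mc$lattice, cutoff = 4.0)
      expect_identical(got$contacting, mc$truth$contacting)
    }
  }
})

test_that("contacts grow monotonically with the cutoff and survive rigid
           translation of a P1 lattice", {
  mc <- generateMiniCrystal(miniCrystalSpec(nResidues = 10, gap = 3.6))
  narrow <- detectContacts(mc$lattice, cutoff = 3.0)$contacting
  wide <- detectContacts(mc$lattice, cutoff = 6.0)$contacting
  expect_true(all(wide[narrow]))

  shifted <- mc$lattice
  at <- atoms(shifted)
  at$x <- at$x + 7.3; at$y <- at$y - 2.1; at$z <- at$z + 4.4
  shifted@atoms <- at
  expect_identical(detectContacts(shifted, cutoff = 4.0)$contacting,
                   detectContacts(mc$lattice, cutoff = 4.0)$contacting)
})

test_that("mini-crystal PDB files round-trip through readLattice", {
  mc <- generateMiniCrystal(miniCrystalSpec(nResidues = 7, gap = 3.5,
                                            spaceGroup = "P21"))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLatticePDB(mc$lattice, tmp)
  back <- readLattice(tmp)
  expect_equal(cellParameters(back), cellParameters(mc$lattice))
  expect_identical(detectContacts(back, 4.0)$contacting,
                   mc$truth$contacting)
  nocryst <- withr::local_tempfile(fileext = ".pdb")
  writeLines(grep("^CRYST1", readLines(tmp), value = TRUE, invert = TRUE),
             nocryst)
  expect_error(readLattice(nocryst), "CRYST1")
})
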