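test_that("SMILES parsing yields correct formula and carbon classes", {
  eth <- parse_smiles("CCO")
  expect_equal(eth$formula, "C2H6O")
  expect_length(eth$carbon_classes, 2)
  expect_length(eth$conformers, 0)

  ethane <- parse_smiles("CC")
  expect_length(ethane$carbon_classes, 1)   # two equivalent carbons

  expect_length(parse_smiles("c1ccccc1")$carbon_classes, 1)
  expect_length(parse_smiles("Cc1ccccc1")$carbon_classes, 5)
  expect_length(parse_smiles("CCCO")$carbon_classes, 3)
})

test_that("equivalence classes agree with exhaustive automorphism search", {
  smis <- c("Cc1ccccc1", "Cc1ccc(C)cc1", "c1ccc2ccccc2c1", "c1ccoc1",
            "CC(C)CC(C)(C)C", "CCOCC", "CC(C)=O", "Clc1ccccc1", "C1CCNC1")
  for (s in smis) {
    mol <- parse_smiles(s)
    expect_identical(carbon_equivalence(mol), brute_carbon_orbits(mol),
                     label = paste("orbits of", s))
  }
  # and on decorated fixtures
  for (mol in fixture_molecules(15, seed = 4)) {
    if (nrow(mol$atoms) <= 12)
      expect_identical(carbon_equivalence(mol), brute_carbon_orbits(mol),
                       label = paste("orbits of", mol$name))
  }
})

test_that("equivalence partition covers every carbon exactly once", {
  for (mol in fixture_molecules(25, seed = 8)) {
    carbons <- which(mol$atoms$element == "C")
    expect_setequal(unlist(mol$carbon_classes), carbons)
    expect_false(any(duplicated(unlist(mol$carbon_classes))))
  }
})

test_that("formula is invariant under atom reordering", {
  mol <- parse_smiles("CC(C)c1ccc(O)cc1")
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  inv <- order(perm)
  rec2 <- mol_record(mol$atoms$element[perm],
                     data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                                order = mol$bonds$order),
                     nH = mol$atoms$nH[perm])
  expect_equal(rec2$formula, mol$formula)
  expect_equal(lengths(rec2$carbon_classes) |> sort(),
               lengths(mol$carbon_classes) |> sort())
})

test_that("SDF round-trip preserves structure, formula and classes", {
  mols <- generate_conformers(
    list(parse_smiles("CCO"), parse_smiles("Cc1ccccc1"),
         parse_smiles("CC(=O)OC")), n_conf = 1, seed = 42)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_structures(mols, path)
  back <- read_structures(path, "sdf")
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(nrow(back[[k]]$atoms), nrow(mols[[k]]$atoms))
    expect_equal(back[[k]]$bonds, mols[[k]]$bonds)
    expect_equal(back[[k]]$formula, mols[[k]]$formula)
    expect_identical(back[[k]]$carbon_classes, mols[[k]]$carbon_classes)
  }
})

test_that("empty and partly bad structure files are handled loudly", {
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  expect_warning(out <- read_structures(empty, "smiles"), "empty")
  expect_length(out, 0)

  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "not_a_smiles((", "CCC"), bad)
  expect_warning(out <- read_structures(bad, "smiles"), "line 2")
  expect_length(out, 2)

  expect_error(read_structures("no/such/file.sdf", "sdf"), "not found")
})

test_that("spectrum CSV and JSON round-trips preserve order and assignment", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("128.5", "77.2", "21.0"), csv)
  sp <- read_spectrum(csv)
  expect_equal(sp$shifts, c(128.5, 77.2, 21.0))
  expect_null(sp$assignment)

  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(shift_spectrum(c(10.1, 55.9), c(2L, 1L)), csv2)
  sp2 <- read_spectrum(csv2)
  expect_equal(sp2$shifts, c(10.1, 55.9))
  expect_equal(sp2$assignment, c(2L, 1L))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(shifts = c(1.5, 2.5),
                            assignment = list(`1` = 2, `2` = 1)),
                       js, auto_unbox = TRUE)
  sp3 <- read_spectrum(js)
  expect_equal(sp3$assignment, c(2L, 1L))

  badrow <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("12.0", "abc"), badrow)
  expect_error(read_spectrum(badrow), "row 2")
})

test_that("bond validation rejects self-loops and out-of-range indices", {
  expect_error(mol_record(c("C", "C"), data.frame(i = 1, j = 1, order = 1)),
               "distinct")
  expect_error(mol_record(c("C", "C"), data.frame(i = 1, j = 3, order = 1)),
               "existing")
})
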