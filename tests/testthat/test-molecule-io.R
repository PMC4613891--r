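test_that("a PDB file with mixed entities loads as one molecule", {
  mol <- read_structure(fixture_pdb_small())
  expect_s3_class(mol, "eem_molecule")
  expect_equal(n_atoms(mol), 11L)
  expect_equal(nrow(mol$residues), 3L)
  expect_equal(mol$total_charge, 0L)          # neutral by default
  expect_equal(mol$atoms$element[1:5], c("N", "C", "C", "O", "H"))
  expect_equal(mol$residues$resname, c("ALA", "GLY", "HOH"))
})

test_that("multi-model PDB files load model 1 only, keeping deuterium distinct", {
  mol <- read_structure(fixture_pdb_models())
  expect_equal(n_atoms(mol), 2L)
  expect_equal(mol$atoms$x, c(0, 1))          # model 1 coordinates
  expect_equal(mol$atoms$element[2], "D")     # not folded into H
})

test_that("altlocs resolve to the highest occupancy, ties first-in-file", {
  mol <- read_structure(fixture_pdb_altloc())
  expect_equal(n_atoms(mol), 2L)
  expect_equal(mol$atoms$x[mol$atoms$name == "CB"], 1.2)  # occ 0.6 wins
})

test_that("element inference from atom names follows PDB conventions and fails on ambiguity", {
  # standard residue, no element column: CA is an alpha carbon
  p <- write_tmp(c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                   pdb_line(2, "1HB", "ALA", "A", 1, 1, 1, 0), "END"), ".pdb")
  mol <- read_structure(p)
  expect_equal(mol$atoms$element, c("C", "H"))
  # monoatomic-ion convention: name == residue name
  p2 <- write_tmp(c(pdb_line(1, "NA", "NA", "A", 1, 0, 0, 0, record = "HETATM"),
                    "END"), ".pdb")
  expect_equal(read_structure(p2)$atoms$element, "Na")
  # unknown ligand with a name readable two ways must fail loudly
  p3 <- write_tmp(c(pdb_line(1, "CA", "XYZ", "A", 1, 0, 0, 0, record = "HETATM"),
                    "END"), ".pdb")
  expect_error(read_structure(p3), "ambiguous")
})

test_that("single-atom MOL and multi-record SDF reads behave per contract", {
  mol <- read_structure(fixture_mol_single_carbon())
  expect_equal(n_atoms(mol), 1L)
  expect_equal(mol$atoms$element, "C")
  expect_equal(mol$total_charge, 0L)

  path <- fixture_sdf_multi(45)
  # independent record count: text scan for the record delimiter
  expect_equal(sum(grepl("^\\$\\$\\$\\$", readLines(path))), 45L)
  mols <- read_structure_multi(path)
  expect_length(mols, 45L)
  expect_equal(vapply(mols, function(m) m$title, character(1)),
               paste0("record", 1:45))          # order preserved
  expect_warning(first <- read_structure(path), "45 records")
  expect_equal(first$atoms$x, mols[[1]]$atoms$x)
  # bond block parsed: the C=O double bond gives multiplicity 2 on both atoms
  expect_equal(eemkit:::atom_multiplicities(mols[[1]]), c(2L, 2L))
})

test_that("format and element errors carry diagnostics", {
  expect_error(read_structure(write_tmp("", ".xyz")), "unknown structure format")
  expect_error(read_structure(write_tmp(character(0), ".pdb")), "empty input")
  bad_mol <- write_tmp(c("bad", "", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 Xx  0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END"), ".mol")
  expect_error(read_structure(bad_mol), "element")
})

test_that("strip_waters removes water residues, is idempotent, keeps total charge", {
  mol <- read_structure(fixture_pdb_small())
  mol$total_charge <- 2L
  dry <- strip_waters(mol)
  expect_equal(n_atoms(dry), 10L)
  expect_equal(nrow(dry$residues), 2L)
  expect_equal(dry$total_charge, 2L)
  expect_identical(strip_waters(dry), dry)      # idempotent / no-water identity
  # all-water molecule: empty result surfaces as an error downstream
  only_water <- eemkit:::subset_atoms(mol, 11L)
  wet0 <- strip_waters(only_water)
  expect_equal(n_atoms(wet0), 0L)
  expect_error(solve_full_eem(wet0, fixture_params()), "empty molecule")
})

test_that("write/read round-trips preserve charges in MOL2, PQR and tabular form", {
  mol <- strip_waters(read_structure(fixture_pdb_small()))
  q <- round(seq(-0.45, 0.45, length.out = n_atoms(mol)), 4)
  cs <- charge_set(q)
  for (ext in c(".mol2", ".pqr", ".chg")) {
    path <- tempfile(fileext = ext)
    write_charges(mol, cs, path)
    back <- read_charge_file(path)
    expect_equal(back$values, q, tolerance = 1e-8,
                 info = paste("round-trip via", ext))
  }
  # MOL2 dialect: USER_CHARGES header present
  mol2 <- tempfile(fileext = ".mol2")
  write_charges(mol, cs, mol2)
  expect_true(any(grepl("USER_CHARGES", readLines(mol2))))
  # all-zero charges survive
  z <- tempfile(fileext = ".mol2")
  write_charges(mol, charge_set(rep(0, n_atoms(mol))), z)
  expect_true(all(read_charge_file(z)$values == 0))
  # structure round-trip: atom count, elements, coordinates to print precision
  back_mol <- read_structure(mol2)
  expect_equal(n_atoms(back_mol), n_atoms(mol))
  expect_equal(back_mol$atoms$element, mol$atoms$element)
  expect_equal(back_mol$atoms$x, mol$atoms$x, tolerance = 1e-4)
})

test_that("charge writing and reading reject malformed input", {
  mol <- read_structure(fixture_mol_single_carbon())
  expect_error(write_charges(mol, charge_set(c(0.1, 0.2)), tempfile(fileext = ".chg")),
               "dimension error")
  bad <- write_tmp(c("index name chain resnum resname charge",
                     "1 C1 A 1 LIG 0.10",
                     "2 O1 A 1 LIG oops"), ".chg")
  expect_error(read_charge_file(bad), "line 3")
})

test_that("generated molecules survive a PDB write/read cycle", {
  g <- generate_globule(60, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_pdb(g, path)
  back <- read_structure(path)
  expect_equal(n_atoms(back), 60L)
  expect_equal(back$atoms$element, g$atoms$element)
  expect_equal(coords(back), coords(g), tolerance = 1e-3)  # PDB prints 3 decimals
  expect_equal(nrow(back$residues), nrow(g$residues))
})
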