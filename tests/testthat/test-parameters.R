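test_that("XML parameter sets load, validate, and round-trip exactly", {
  xml <- write_tmp(c(
    '<ParameterSet Name="mini" Kappa="0.5">',
    '  <Element Symbol="H"><Parameters A="2.4" B="8.0"/></Element>',
    '</ParameterSet>'), ".xml")
  set <- load_parameter_set_xml(xml)
  expect_equal(set$name, "mini")
  expect_equal(set$kappa, 0.5)
  expect_equal(nrow(set$entries), 1L)
  expect_equal(set$entries$A, 2.4)

  # 5-element set, element granularity throughout
  xml5 <- write_tmp(c(
    '<ParameterSet Name="five" Kappa="0.31">',
    sprintf('  <Element Symbol="%s"><Parameters A="%g" B="%g"/></Element>',
            c("H", "C", "N", "O", "S"), 2:6 + 0.123456789, 7:11 + 0.987654321),
    '</ParameterSet>'), ".xml")
  set5 <- load_parameter_set_xml(xml5)
  expect_equal(nrow(set5$entries), 5L)
  expect_true(all(is.na(set5$entries$mult)))

  # save -> load round-trip is exact to full precision
  out <- tempfile(fileext = ".xml")
  save_parameter_set_xml(set5, out)
  again <- load_parameter_set_xml(out)
  expect_identical(again$entries, set5$entries)
  expect_identical(again$kappa, set5$kappa)
  expect_identical(again$name, set5$name)

  # bond-granularity round-trip
  reg <- builtin_parameter_sets()
  bset <- reg$synthetic_organic_bonds
  out2 <- tempfile(fileext = ".xml")
  save_parameter_set_xml(bset, out2)
  expect_identical(load_parameter_set_xml(out2)$entries, bset$entries)
})

test_that("invalid parameter XML is rejected with a located diagnostic", {
  dup <- write_tmp(c(
    '<ParameterSet Name="dup" Kappa="0.5">',
    '  <Element Symbol="C"><Bond Type="2" A="4" B="8"/><Bond Type="2" A="5" B="9"/></Element>',
    '</ParameterSet>'), ".xml")
  expect_error(load_parameter_set_xml(dup), "duplicate")
  badB <- write_tmp(c(
    '<ParameterSet Name="b" Kappa="0.5">',
    '  <Element Symbol="C"><Parameters A="4" B="-8"/></Element>',
    '</ParameterSet>'), ".xml")
  expect_error(load_parameter_set_xml(badB), "B must be positive")
  badK <- write_tmp('<ParameterSet Name="k" Kappa="0"><Element Symbol="C"><Parameters A="4" B="8"/></Element></ParameterSet>', ".xml")
  expect_error(load_parameter_set_xml(badK), "Kappa must be positive")
  notroot <- write_tmp("<Nope/>", ".xml")
  expect_error(load_parameter_set_xml(notroot), "root element")
  mixed <- write_tmp(c(
    '<ParameterSet Name="m" Kappa="0.5">',
    '  <Element Symbol="C"><Parameters A="4" B="8"/></Element>',
    '  <Element Symbol="N"><Bond Type="1" A="5" B="9"/></Element>',
    '</ParameterSet>'), ".xml")
  expect_error(load_parameter_set_xml(mixed), "mixed granularity")
})

test_that("derive_alias duplicates parameters across elements (H -> D)", {
  set <- fixture_params()
  ali <- derive_alias(set, "H", "D")
  h <- set$entries[set$entries$element == "H", c("A", "B")]
  d <- ali$entries[ali$entries$element == "D", c("A", "B")]
  expect_equal(unlist(d), unlist(h), ignore_attr = TRUE)  # D identical to H
  expect_identical(derive_alias(set, "C", "C")$entries, set$entries)
  expect_warning(derive_alias(ali, "C", "D"), "overwriting")
  expect_error(derive_alias(set, "Zn", "D"), "missing parameter")
  # aliased set solves a D-containing molecule
  mol <- fixture_diatomic(1.2, c("D", "O"))
  expect_error(solve_full_eem(mol, set), "not applicable")
  expect_silent(solve_full_eem(mol, ali))
})

test_that("applicability reports cover/missing atom types", {
  set <- fixture_params(c("H", "C", "N", "O"))
  mol <- generate_globule(30, element_freqs = c(H = 0.5, C = 0.3, O = 0.2),
                          seed = 5)
  rep <- check_applicability(set, mol)
  expect_true(rep$applicable)
  expect_equal(nrow(rep$missing), 0L)

  molCl <- mol
  molCl$atoms$element[1] <- "Cl"          # a chlorinated compound
  repCl <- check_applicability(set, molCl)
  expect_false(repCl$applicable)
  expect_true("Cl" %in% repCl$missing$element)

  empty <- eemkit:::subset_atoms(mol, integer(0))
  expect_true(check_applicability(set, empty)$applicable)  # vacuous
})

test_that("applicability is monotone under atom removal", {
  set <- fixture_params(c("H", "C"))
  mol <- generate_globule(40, seed = 3)   # contains H,C,N,O
  before <- check_applicability(set, mol)
  for (k in c(30, 20, 10, 5)) {
    sub <- eemkit:::subset_atoms(mol, seq_len(k))
    after <- check_applicability(set, sub)
    expect_true(all(paste(after$missing$element) %in% paste(before$missing$element)))
  }
})

test_that("bond-order-aware sets require bond information", {
  reg <- builtin_parameter_sets()
  bset <- reg$synthetic_organic_bonds
  pdb_mol <- strip_waters(read_structure(fixture_pdb_small()))  # no bonds
  expect_error(check_applicability(bset, pdb_mol), "no bond information")
  sdf_mol <- read_structure_multi(fixture_sdf_multi(1))[[1]]    # has bonds
  rep <- check_applicability(bset, sdf_mol)
  expect_true(rep$applicable)   # C and O at multiplicity 2 are parameterized
})

test_that("default-set selection walks the registry in order", {
  setA <- fixture_params(c("H", "C", "N", "O")); setA$name <- "A"
  setB <- fixture_params(c("H", "C", "N", "O", "S")); setB$name <- "B"
  protein <- generate_globule(30, seed = 2)   # H/C/N/O only
  expect_equal(select_default_set(protein, list(setA, setB))$name, "A")
  expect_equal(select_default_set(protein, list(setB))$name, "B")
  iron <- protein
  iron$atoms$element[1] <- "Fe"
  expect_warning(pick <- select_default_set(iron, list(setA, setB)),
                 "unparameterized")
  expect_equal(pick$name, "A")               # least-missing tie -> first
})
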