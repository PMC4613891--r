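# Fixture builders shared across the test files. Everything is generated in
# code at test time; structure files are written to tempdir().

# fixed-width PDB ATOM/HETATM line
pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     occ = 1, alt = " ", icode = " ", element = "",
                     record = "ATOM") {
  # name placement: cols 13-16, element right-justified in 77-78
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resnum, icode,
          x, y, z, occ, 0, element)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a 3-residue peptide-like fragment (2 x 5-atom residues + 1 water),
# with element columns present
fixture_pdb_small <- function() {
  write_tmp(c(
    pdb_line(1, "N",  "ALA", "A", 1, 11.104, 6.134, -6.504, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147, element = "C"),
    pdb_line(3, "C",  "ALA", "A", 1, 10.729, 6.768, -4.123, element = "C"),
    pdb_line(4, "O",  "ALA", "A", 1,  9.581, 7.111, -4.411, element = "O"),
    pdb_line(5, "H",  "ALA", "A", 1, 11.832, 5.616, -7.212, element = "H"),
    pdb_line(6, "N",  "GLY", "A", 2, 11.201, 7.028, -2.943, element = "N"),
    pdb_line(7, "CA", "GLY", "A", 2, 10.419, 7.698, -1.903, element = "C"),
    pdb_line(8, "C",  "GLY", "A", 2, 10.966, 7.373, -0.517, element = "C"),
    pdb_line(9, "O",  "GLY", "A", 2, 12.112, 6.935, -0.377, element = "O"),
    pdb_line(10, "H", "GLY", "A", 2, 12.151, 6.789, -3.021, element = "H"),
    pdb_line(11, "O", "HOH", "A", 3,  5.000, 5.000,  5.000, element = "O",
             record = "HETATM"),
    "END"), ".pdb")
}

# altloc pair: CB has conformers A (occ 0.4) and B (occ 0.6)
fixture_pdb_altloc <- function() {
  write_tmp(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdb_line(2, "CB", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4, alt = "A", element = "C"),
    pdb_line(3, "CB", "ALA", "A", 1, 1.2, 0, 0, occ = 0.6, alt = "B", element = "C"),
    "END"), ".pdb")
}

# two NMR models; model 2 is translated so a multi-model mixup is detectable
fixture_pdb_models <- function() {
  write_tmp(c(
    "MODEL        1",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    pdb_line(2, "D",  "GLY", "A", 1, 1, 0, 0, element = "D"),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "GLY", "A", 1, 9, 9, 9, element = "C"),
    pdb_line(2, "D",  "GLY", "A", 1, 8, 9, 9, element = "D"),
    "ENDMDL",
    "END"), ".pdb")
}

# single-carbon MOL (V2000) file
fixture_mol_single_carbon <- function() {
  write_tmp(c(
    "methane stub", "  eemkit", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END"), ".mol")
}

# n_rec-record SDF, each a 2-atom C-O pair
fixture_sdf_multi <- function(n_rec) {
  rec <- function(k) c(
    sprintf("record%d", k), "  eemkit", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    sprintf("    %.4f    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0", k * 1.0),
    sprintf("    %.4f    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0", k * 1.0 + 1.2),
    "  1  2  2  0",
    "M  END", "$$$$")
  write_tmp(unlist(lapply(seq_len(n_rec), rec)), ".sdf")
}

# element-granularity parameter set with fixed values, for deterministic math
fixture_params <- function(elements = c("H", "C", "N", "O"),
                           A = NULL, B = NULL, kappa = 0.5) {
  if (is.null(A)) A <- seq(2.5, 7, length.out = length(elements))
  if (is.null(B)) B <- seq(8, 11, length.out = length(elements))
  eem_parameter_set("fixture", kappa,
                    data.frame(element = elements, mult = NA_integer_,
                               A = A, B = B))
}

# diatomic with two distinct elements at distance r
fixture_diatomic <- function(r, elements = c("C", "N")) {
  mol <- generate_chain(2, spacing = r)
  mol$atoms$element <- elements
  mol$atoms$name <- paste0(elements, 1:2)
  mol
}

expect_charge_equal <- function(a, b, tol) {
  expect_lt(max(abs(charge_values(a) - charge_values(b))), tol)
}

charge_values <- eemkit:::charge_values
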