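# The eem_molecule container: the single chemical system EEM acts on.
# Whatever mix of protein / nucleic acid / ligand / water a structure file
# holds is loaded as one molecule; atoms reference residues by row index.

# Recognized element symbols (IUPAC, Z = 1..103) plus deuterium "D", which is
# kept distinct from H: the parameter layer decides its treatment.
.ELEMENTS <- c(
  "H", "D", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
  "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb",
  "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In",
  "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm",
  "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta",
  "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At",
  "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk",
  "Cf", "Es", "Fm", "Md", "No", "Lr")

# residue names treated as water (case-insensitive)
.WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

#' Construct a molecule
#'
#' Builds the molecule container used throughout eemkit: an ordered atom
#' table, an ordered residue table the atoms reference, optional bonds
#' (needed only for bond-order-aware parameter sets), and the total
#' molecular charge that the EEM calculation distributes over the atoms.
#'
#' @param atoms data.frame with columns `element` (normalized symbol),
#'   `name` (atom name from the source file), `x`, `y`, `z` (Angstrom) and
#'   `resid` (integer row index into `residues`). Optional extra columns
#'   (`serial`, `altloc`, `occupancy`, `sybyl_type`) are retained.
#' @param residues data.frame with columns `chain`, `resnum`, `icode`,
#'   `resname`.
#' @param bonds optional data.frame with columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2, 3; aromatic encoded as 2).
#' @param total_charge integer total molecular charge in units of e.
#'   Molecules are assumed neutral unless stated otherwise.
#' @param source character of length 2: file name and format tag (or
#'   whatever provenance is available).
#' @return An object of class `eem_molecule`.
#' @export
eem_molecule <- function(atoms, residues, bonds = NULL, total_charge = 0L,
                         source = c(file = NA_character_, format = NA_character_)) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  required <- c("element", "name", "x", "y", "z", "resid")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) < 1L)
    stop("empty molecule: a molecule must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atomic coordinates")
  bad <- which(!(atoms$element %in% .ELEMENTS))
  if (length(bad))
    stop("unrecognized element symbol '", atoms$element[bad[1]],
         "' for atom ", bad[1], " (name '", atoms$name[bad[1]], "')")
  if (any(atoms$resid < 1L | atoms$resid > nrow(residues)))
    stop("atom references a residue outside the residue table")
  if (length(total_charge) != 1L || !is.finite(total_charge) ||
      total_charge != round(total_charge))
    stop("total_charge must be a single integer (units of e)")
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues, bonds = bonds,
                 total_charge = as.integer(total_charge), source = source),
            class = "eem_molecule")
}

#' Number of atoms in a molecule
#' @param mol an `eem_molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atomic coordinates as a matrix
#' @param mol an `eem_molecule`.
#' @return numeric N x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' @export
print.eem_molecule <- function(x, ...) {
  cat("eem_molecule:", n_atoms(x), "atoms,", nrow(x$residues), "residues,",
      "total charge", x$total_charge, "e\n")
  cat("  elements:", paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                           collapse = " "), "\n")
  if (!is.na(x$source[1])) cat("  source:", x$source[1], "\n")
  invisible(x)
}

# normalize an element symbol: case-fix ("FE" -> "Fe", "cl" -> "Cl");
# returns NA when the result is not a recognized element
normalize_element <- function(sym) {
  sym <- trimws(sym)
  out <- ifelse(nchar(sym) == 0, NA_character_,
                paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym)))))
  out[!(out %in% .ELEMENTS)] <- NA_character_
  out
}

is_water_residue <- function(resname) toupper(trimws(resname)) %in% .WATER_NAMES

#' Remove water molecules
#'
#' Drops all atoms belonging to water residues (HOH, WAT, H2O, DOD;
#' case-insensitive) and re-indexes the remaining atoms contiguously.
#' The total molecular charge is left unchanged. Idempotent; a molecule
#' without waters is returned as-is. A molecule consisting only of waters
#' yields an object with zero atoms, which any downstream EEM solve
#' rejects as an empty molecule.
#'
#' @param mol an `eem_molecule`.
#' @return an `eem_molecule` without water atoms.
#' @export
strip_waters <- function(mol) {
  stopifnot(inherits(mol, "eem_molecule"))
  water_res <- which(is_water_residue(mol$residues$resname))
  if (!length(water_res)) return(mol)
  keep_atom <- !(mol$atoms$resid %in% water_res)
  subset_atoms(mol, which(keep_atom))
}

# Subset a molecule to the given atom indices (in order), dropping unused
# residues and remapping bond/residue indices. Used by strip_waters,
# altloc resolution and make_dissociated. Deliberately tolerates a
# zero-atom result so degenerate paths surface downstream.
subset_atoms <- function(mol, keep) {
  atoms <- mol$atoms[keep, , drop = FALSE]
  used_res <- sort(unique(atoms$resid))
  res_map <- integer(nrow(mol$residues))
  res_map[used_res] <- seq_along(used_res)
  atoms$resid <- res_map[atoms$resid]
  residues <- mol$residues[used_res, , drop = FALSE]
  bonds <- mol$bonds
  if (!is.null(bonds) && nrow(bonds)) {
    atom_map <- integer(n_atoms(mol))
    atom_map[keep] <- seq_along(keep)
    ok <- bonds$i %in% keep & bonds$j %in% keep
    bonds <- bonds[ok, , drop = FALSE]
    bonds$i <- atom_map[bonds$i]
    bonds$j <- atom_map[bonds$j]
    rownames(bonds) <- NULL
  }
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues, bonds = bonds,
                 total_charge = mol$total_charge, source = mol$source),
            class = "eem_molecule")
}

# highest bond order incident to each atom (aromatic already encoded as 2);
# atoms with no bonds get multiplicity 1. NULL when the molecule carries no
# bond information at all.
atom_multiplicities <- function(mol) {
  if (is.null(mol$bonds)) return(NULL)
  mult <- rep(1L, n_atoms(mol))
  b <- mol$bonds
  if (nrow(b)) {
    ord <- pmin(as.integer(b$order), 3L)
    for (k in seq_len(nrow(b))) {
      mult[b$i[k]] <- max(mult[b$i[k]], ord[k])
      mult[b$j[k]] <- max(mult[b$j[k]], ord[k])
    }
  }
  mult
}
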