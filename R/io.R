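# Structure I/O: PDB, PQR, MOL, MOL2 and SDF readers feeding the unified
# eem_molecule container, plus charge-annotated writers (MOL2 with
# USER_CHARGES, PQR, and a plain tabular format) and their readers.
#
# Parsing of the standard formats is delegated to bio3d (PDB/PQR/MOL2) and
# ChemmineR (MOL/SDF). The MOL2 writer is local so the dialect is fixed:
# charge_type USER_CHARGES, coordinates and charges to 4 decimals.

.STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HOH", "WAT", "DOD", "H2O", "ACE", "NME", "NMA", "MSE",
  "DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U", "T")

.ORGANIC_SINGLE <- c("H", "C", "N", "O", "P", "S")

# Derive an element from a PDB/PQR atom name when the file carries no element
# column. Follows PDB v3 naming conventions as far as they survive trimming;
# ambiguous names fail loudly rather than guess.
infer_element_from_name <- function(name, resname, atom_index) {
  nm0 <- toupper(trimws(name))
  res <- toupper(trimws(resname))
  fail <- function(why) {
    stop("cannot infer element for atom ", atom_index, " (name '", name,
         "', residue '", resname, "'): ", why)
  }
  if (!nchar(nm0)) fail("empty atom name")
  # monoatomic-ion convention: atom name equals residue name (NA, CL, FE, ...)
  if (nm0 == res) {
    el <- normalize_element(nm0)
    if (!is.na(el)) return(el)
  }
  nm <- sub("^[0-9]+", "", nm0)       # leading digits (e.g. 1HB2)
  if (!nchar(nm)) fail("name contains no letters")
  first <- normalize_element(substr(nm, 1, 1))
  if (res %in% .STANDARD_RESIDUES) {
    # standard residues contain only the organic single-letter elements
    if (!is.na(first) && first %in% .ORGANIC_SINGLE) return(first)
    fail("non-organic first letter in a standard residue")
  }
  if (!grepl("[0-9]", nm) && nchar(nm) == 2) {
    two <- normalize_element(nm)
    if (!is.na(two)) {
      if (!is.na(first))
        fail(paste0("ambiguous between '", first, "' and '", two,
                    "'; supply an element column"))
      return(two)
    }
  }
  if (!is.na(first)) return(first)
  fail("no recognizable element symbol")
}

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", ent = "pdb",
         pqr = "pqr",
         mol2 = "mol2", ml2 = "mol2",
         sdf = "sdf", sd = "sdf",
         mol = "mol",
         chg = "chg",
         stop("unknown structure format for file '", path,
              "' (extension '.", ext, "'); pass `format` explicitly"))
}

#' Read a molecular structure file
#'
#' Loads a structure in PDB, PQR, MOL (V2000), MOL2 or SDF format as a
#' single molecule: every chemical entity in the file (protein, nucleic
#' acid, ligands, waters) becomes part of one `eem_molecule`. For
#' multi-model PDB files (NMR ensembles) only the first model is used.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken first-in-file). Elements are normalized; deuterium is kept
#' as the distinct element "D". Multi-record SDF files: only the first
#' record is returned, with a warning (use [read_structure_multi()]).
#'
#' The total molecular charge of the returned molecule is 0: molecules are
#' assumed neutral, and the caller must set `total_charge` for ions.
#'
#' @param path file path.
#' @param format optional format tag ("pdb", "pqr", "mol", "mol2", "sdf");
#'   inferred from the extension when omitted.
#' @return an [eem_molecule()].
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input: '", path, "' has no content")
  format <- if (is.null(format)) format_from_path(path) else match.arg(
    format, c("pdb", "pqr", "mol", "mol2", "sdf"))
  mol <- switch(format,
                pdb  = read_structure_pdb(path, pqr = FALSE),
                pqr  = read_structure_pdb(path, pqr = TRUE),
                mol2 = read_structure_mol2(path),
                mol  = ,
                sdf  = {
                  mols <- read_structure_sdf(path)
                  if (length(mols) > 1L)
                    warning("'", path, "' holds ", length(mols),
                            " records; returning the first (see read_structure_multi)")
                  mols[[1L]]
                })
  mol$source <- c(file = path, format = format)
  mol
}

#' Read all records of a multi-record SDF file
#'
#' @param path file path to an SDF (or single-record MOL) file.
#' @return list of [eem_molecule()] objects, record order preserved.
#' @export
read_structure_multi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  mols <- read_structure_sdf(path)
  for (i in seq_along(mols)) mols[[i]]$source <- c(file = path, format = "sdf")
  mols
}

# -- PDB / PQR ---------------------------------------------------------------

read_structure_pdb <- function(path, pqr = FALSE) {
  at <- if (pqr) {
    suppressWarnings(bio3d::read.pqr(path, verbose = FALSE))$atom
  } else {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE))$atom
  }
  if (is.null(at) || nrow(at) == 0L) stop("empty input: no atoms in '", path, "'")

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  if (is.null(at$o)) at$o <- 1
  occ <- if (pqr) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)

  # altloc resolution: within each (chain, resno, insert, atom name) group
  # keep the highest-occupancy record; ties -> first in file
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep_first <- !duplicated(key[ord])
    keep <- sort(ord[keep_first])
    at <- at[keep, , drop = FALSE]
    occ <- occ[keep]
  }

  elesy <- if (pqr) rep(NA_character_, nrow(at)) else at$elesy
  element <- normalize_element(ifelse(is.na(elesy), "", elesy))
  # deuterium survives case-fixing but must not be produced accidentally:
  # bio3d reports the element column verbatim, so "D" means the file said D
  need <- which(is.na(element))
  for (i in need)
    element[i] <- infer_element_from_name(at$elety[i], at$resid[i], i)

  res_key <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
  resid_idx <- match(res_key, unique(res_key))
  ures <- !duplicated(res_key)
  residues <- data.frame(chain = at$chain[ures], resnum = at$resno[ures],
                         icode = at$insert[ures], resname = at$resid[ures],
                         stringsAsFactors = FALSE)
  atoms <- data.frame(element = element, name = at$elety,
                      x = at$x, y = at$y, z = at$z, resid = resid_idx,
                      serial = at$eleno, altloc = at$alt, occupancy = occ,
                      stringsAsFactors = FALSE)
  extra <- list(charges = if (pqr) at$o else NULL, radii = if (pqr) at$b else NULL)
  mol <- eem_molecule(atoms, residues, bonds = NULL, total_charge = 0L)
  mol$pqr_extra <- extra
  mol
}

# -- MOL2 --------------------------------------------------------------------

mol2_bond_order <- function(type) {
  ifelse(type %in% c("1", "2", "3"), suppressWarnings(as.integer(type)),
         ifelse(type == "ar", 2L, 1L))  # aromatic counts as 2; am/du/un -> 1
}

read_structure_mol2 <- function(path) {
  # bond-less MOL2 (point-cloud output) is legitimate; silence the reader's nag
  m <- suppressWarnings(bio3d::read.mol2(path))
  at <- m$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty input: no atoms in '", path, "'")
  element <- normalize_element(sub("\\..*$", "", at$elety))
  bad <- which(is.na(element))
  if (length(bad))
    stop("unrecognizable element for atom ", bad[1], " (SYBYL type '",
         at$elety[bad[1]], "') in '", path, "'")
  if (is.null(at$resno)) at$resno <- 1
  if (is.null(at$resid)) at$resid <- "LIG"
  res_key <- paste(at$resno, at$resid, sep = "\r")
  resid_idx <- match(res_key, unique(res_key))
  ures <- !duplicated(res_key)
  residues <- data.frame(chain = "A", resnum = at$resno[ures], icode = "",
                         resname = at$resid[ures], stringsAsFactors = FALSE)
  atoms <- data.frame(element = element, name = at$elena,
                      x = at$x, y = at$y, z = at$z, resid = resid_idx,
                      serial = at$eleno, altloc = "", occupancy = 1,
                      sybyl_type = at$elety, stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond)) {
    bonds <- data.frame(i = as.integer(m$bond$origin),
                        j = as.integer(m$bond$target),
                        order = mol2_bond_order(m$bond$type))
  }
  mol <- eem_molecule(atoms, residues, bonds = bonds, total_charge = 0L)
  mol$mol2_charges <- at$charge
  mol
}

# -- MOL / SDF ---------------------------------------------------------------

# Fixed-column V2000 record parser, used when the SDF reader rejects a
# record it cannot represent (notably molecules with zero bonds).
parse_v2000_record <- function(rl, k, path) {
  if (length(rl) < 5L) stop("empty input: record ", k, " of '", path,
                            "' is not a V2000 block")
  counts <- rl[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1L)
    stop("empty input: record ", k, " of '", path, "' has no atoms")
  al <- rl[5:(4 + natoms)]
  xyz <- vapply(c(1, 11, 21), function(s)
    as.numeric(substr(al, s, s + 9)), numeric(natoms))
  xyz <- matrix(xyz, ncol = 3)
  sym <- trimws(substr(al, 32, 34))
  bonds <- NULL
  if (!is.na(nbonds) && nbonds > 0L) {
    bl <- rl[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = pmin(as.integer(substr(bl, 7, 9)), 3L))
  }
  list(sym = sym, xyz = xyz, bonds = bonds, title = trimws(rl[1]))
}

read_structure_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) stop("empty input: '", path, "' has no content")
  # a bare MOL file has no record terminator; add one for the SDF reader
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  records <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  records <- records[vapply(records, function(r) any(nzchar(trimws(r))), logical(1))]

  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  valid <- suppressWarnings(ChemmineR::validSDF(sdfs))
  ids <- ChemmineR::sdfid(sdfs)
  if (length(sdfs) != length(records))
    valid <- rep(FALSE, length(records))  # reader disagreed on record count

  lapply(seq_along(records), function(k) {
    if (isTRUE(valid[k])) {
      sdf <- sdfs[[k]]
      ab <- ChemmineR::atomblock(sdf)
      sym <- sub("_.*$", "", rownames(ab))
      xyz <- ab[, 1:3, drop = FALSE]
      bb <- ChemmineR::bondblock(sdf)
      bonds <- NULL
      if (!is.null(bb) && nrow(bb))
        bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                            order = pmin(as.integer(bb[, 3]), 3L))
      title <- if (length(ids) >= k && !is.na(ids[k])) ids[k] else ""
    } else {
      rec <- parse_v2000_record(records[[k]], k, path)
      sym <- rec$sym; xyz <- rec$xyz; bonds <- rec$bonds; title <- rec$title
    }
    element <- normalize_element(sym)
    bad <- which(is.na(element))
    if (length(bad))
      stop("unrecognizable element for atom ", bad[1], " (symbol '",
           sym[bad[1]], "') in record ", k, " of '", path, "'")
    n <- length(element)
    atoms <- data.frame(element = element,
                        name = paste0(element, seq_len(n)),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        resid = 1L, serial = seq_len(n), altloc = "",
                        occupancy = 1, stringsAsFactors = FALSE)
    residues <- data.frame(chain = "A", resnum = 1L, icode = "",
                           resname = "LIG", stringsAsFactors = FALSE)
    mol <- eem_molecule(atoms, residues, bonds = bonds, total_charge = 0L)
    mol$title <- title
    mol
  })
}

# -- charge-annotated output -------------------------------------------------

#' Write a structure annotated with charges
#'
#' Writes the molecule with one charge per atom in one of three formats:
#' `"mol2"` (charges in the per-atom charge column, charge type
#' `USER_CHARGES`, coordinates and charges to 4 decimals), `"pqr"`
#' (charges in the PQR charge field), or `"chg"`, a plain whitespace
#' table with header `index name chain resnum resname charge`. All three
#' round-trip through [read_charge_file()].
#'
#' @param mol an [eem_molecule()].
#' @param charges a [charge_set()] or numeric vector, one value per atom.
#' @param path output file path.
#' @param format "mol2", "pqr" or "chg"; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_charges <- function(mol, charges, path, format = NULL) {
  stopifnot(inherits(mol, "eem_molecule"))
  q <- charge_values(charges)
  if (length(q) != n_atoms(mol))
    stop("dimension error: ", length(q), " charges for ", n_atoms(mol), " atoms")
  format <- if (is.null(format)) format_from_path(path) else match.arg(
    format, c("mol2", "pqr", "chg"))
  switch(format,
         mol2 = write_mol2_charges(mol, q, path),
         pqr  = write_pqr_charges(mol, q, path),
         chg  = write_chg_table(mol, q, path))
  invisible(path)
}

write_mol2_charges <- function(mol, q, path) {
  at <- mol$atoms
  res <- mol$residues[at$resid, , drop = FALSE]
  stype <- if (!is.null(at$sybyl_type)) at$sybyl_type else at$element
  nb <- if (!is.null(mol$bonds)) nrow(mol$bonds) else 0L
  lines <- c(
    "@<TRIPOS>MOLECULE",
    if (!is.null(mol$title) && nzchar(mol$title)) mol$title else "eemkit",
    sprintf("%d %d %d 0 0", n_atoms(mol), nb, nrow(mol$residues)),
    "SMALL",
    "USER_CHARGES",
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %5d %-8s %10.4f",
            seq_len(n_atoms(mol)), at$name, at$x, at$y, at$z, stype,
            at$resid, paste0(trimws(res$resname), res$resnum), q))
  if (nb > 0L) {
    lines <- c(lines, "@<TRIPOS>BOND",
               sprintf("%6d %5d %5d %s", seq_len(nb), mol$bonds$i,
                       mol$bonds$j, as.character(mol$bonds$order)))
  }
  writeLines(lines, path)
}

write_pqr_charges <- function(mol, q, path) {
  at <- mol$atoms
  res <- mol$residues[at$resid, , drop = FALSE]
  radii <- if (!is.null(mol$pqr_extra$radii)) mol$pqr_extra$radii
           else rep(1.5, n_atoms(mol))
  bio3d::write.pqr(xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = res$resnum, resid = res$resname,
                   eleno = seq_len(n_atoms(mol)), elety = at$name,
                   chain = res$chain, o = q, b = radii, file = path)
}

write_chg_table <- function(mol, q, path) {
  at <- mol$atoms
  res <- mol$residues[at$resid, , drop = FALSE]
  df <- data.frame(index = seq_len(n_atoms(mol)), name = at$name,
                   chain = ifelse(nzchar(res$chain), res$chain, "."),
                   resnum = res$resnum, resname = res$resname,
                   charge = sprintf("%.6f", q))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
}

#' Read a charge set from a file
#'
#' Reads per-atom charges, in atom order, from a MOL2 file (charge
#' column), a PQR file (charge field) or the plain tabular format written
#' by [write_charges()].
#'
#' @param path file path (.mol2, .pqr or .chg; content is sniffed when the
#'   extension is unknown).
#' @return a [charge_set()] with job method `"file"`.
#' @export
read_charge_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  format <- if (ext %in% c("mol2", "ml2")) "mol2"
            else if (ext == "pqr") "pqr"
            else if (ext == "chg") "chg"
            else {
              head <- readLines(path, n = 5L, warn = FALSE)
              if (any(grepl("@<TRIPOS>", head, fixed = TRUE))) "mol2"
              else if (grepl("^index\\s+name", head[1])) "chg"
              else "pqr"
            }
  q <- switch(format,
    mol2 = {
      at <- suppressWarnings(bio3d::read.mol2(path))$atom
      if (is.null(at$charge) || all(is.na(at$charge)))
        stop("format error: no charge column in MOL2 file '", path, "'")
      at$charge
    },
    pqr = {
      at <- suppressWarnings(bio3d::read.pqr(path, verbose = FALSE))$atom
      if (is.null(at$o) || all(is.na(at$o)))
        stop("format error: no charge field in PQR file '", path, "'")
      at$o
    },
    chg = {
      tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
      if (!"charge" %in% names(tab))
        stop("format error: missing charge column in '", path, "'")
      val <- suppressWarnings(as.numeric(tab$charge))
      if (anyNA(val))
        stop("parse error: non-numeric charge on line ",
             which(is.na(val))[1] + 1L, " of '", path, "'")
      val
    })
  charge_set(q, chi_bar = NA_real_,
             job = list(method = "file", parameter_set = NA_character_,
                        radius = NA_real_, precision = NA_integer_,
                        total_charge = sum(q), source = path))
}
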