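# EEM parameter sets: per-atom-type electronegativity (A) and hardness (B)
# parameters plus the set-level distance-coupling constant kappa. Sets are
# either element-granular or bond-order (multiplicity) granular, never mixed.
#
# XML template (attributes are the interface):
#   <ParameterSet Name=".." Kappa="..">
#     <Element Symbol="C">
#       <Parameters A=".." B=".."/>                      element granularity
#       -- or --
#       <Bond Type="1" A=".." B=".."/> <Bond Type="2" ../>  bond granularity
#     </Element>
#   </ParameterSet>

#' Construct an EEM parameter set
#'
#' @param name set name.
#' @param kappa positive distance-coupling constant; `kappa / R` (R in
#'   Angstrom) must carry the units of `B`.
#' @param entries data.frame with columns `element`, `mult` (integer 1-3,
#'   or `NA` for element-granularity sets), `A` and `B`. Either every row
#'   has a multiplicity or none does.
#' @param provenance free-text description (QM reference, target
#'   molecules, literature source).
#' @return an object of class `eem_params`.
#' @export
eem_parameter_set <- function(name, kappa, entries, provenance = "") {
  stopifnot(is.data.frame(entries),
            all(c("element", "mult", "A", "B") %in% names(entries)))
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a single positive number")
  if (any(!is.finite(entries$A)) || any(!is.finite(entries$B)))
    stop("non-finite A/B parameter")
  if (any(entries$B <= 0))
    stop("hardness parameter B must be positive (offending element: ",
         entries$element[which(entries$B <= 0)[1]], ")")
  has_mult <- !is.na(entries$mult)
  if (any(has_mult) && !all(has_mult))
    stop("mixed granularity: either all entries carry a multiplicity or none")
  if (any(has_mult) && !all(entries$mult[has_mult] %in% 1:3))
    stop("multiplicity must be 1, 2 or 3")
  bad <- which(!(entries$element %in% .ELEMENTS))
  if (length(bad))
    stop("unrecognized element symbol in parameter set: ", entries$element[bad[1]])
  key <- paste(entries$element, entries$mult)
  if (anyDuplicated(key))
    stop("duplicate entry for atom type ", entries$element[anyDuplicated(key)],
         " (multiplicity ", entries$mult[anyDuplicated(key)], ")")
  rownames(entries) <- NULL
  structure(list(name = name, kappa = kappa,
                 entries = entries[, c("element", "mult", "A", "B")],
                 provenance = provenance),
            class = "eem_params")
}

#' @export
print.eem_params <- function(x, ...) {
  gran <- if (all(is.na(x$entries$mult))) "element" else "bond-order"
  cat("eem_params '", x$name, "': kappa = ", x$kappa, ", ",
      nrow(x$entries), " atom types (", gran, " granularity)\n", sep = "")
  invisible(x)
}

uses_multiplicity <- function(set) any(!is.na(set$entries$mult))

#' Load an EEM parameter set from its XML template
#'
#' @param path path to a parameter-set XML file.
#' @return an [eem_parameter_set()].
#' @export
load_parameter_set_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "ParameterSet")
    stop("validation error at /", root, ": root element must be <ParameterSet>")
  name <- xml2::xml_attr(doc, "Name")
  kappa <- suppressWarnings(as.numeric(xml2::xml_attr(doc, "Kappa")))
  if (is.na(name)) stop("validation error at /ParameterSet: missing Name attribute")
  if (is.na(kappa)) stop("validation error at /ParameterSet: missing or non-numeric Kappa attribute")
  if (kappa <= 0) stop("value error: Kappa must be positive, got ", kappa)
  prov <- xml2::xml_attr(doc, "Provenance")
  if (is.na(prov)) prov <- ""

  rows <- list()
  for (el in xml2::xml_find_all(doc, "./Element")) {
    sym <- xml2::xml_attr(el, "Symbol")
    if (is.na(sym))
      stop("validation error at /ParameterSet/Element: missing Symbol attribute")
    pars <- xml2::xml_find_all(el, "./Parameters")
    bnds <- xml2::xml_find_all(el, "./Bond")
    if (length(pars) && length(bnds))
      stop("validation error at /ParameterSet/Element[@Symbol='", sym,
           "']: mixed <Parameters> and <Bond> children")
    if (length(pars) > 1L)
      stop("duplicate entry: several <Parameters> for element ", sym)
    if (!length(pars) && !length(bnds))
      stop("validation error at /ParameterSet/Element[@Symbol='", sym,
           "']: no <Parameters> or <Bond> child")
    grab <- function(node, mult) {
      A <- suppressWarnings(as.numeric(xml2::xml_attr(node, "A")))
      B <- suppressWarnings(as.numeric(xml2::xml_attr(node, "B")))
      if (is.na(A) || is.na(B))
        stop("validation error at /ParameterSet/Element[@Symbol='", sym,
             "']: missing or non-numeric A/B attribute")
      if (B <= 0)
        stop("value error: B must be positive for element ", sym, ", got ", B)
      data.frame(element = sym, mult = mult, A = A, B = B)
    }
    if (length(pars)) {
      rows[[length(rows) + 1L]] <- grab(pars[[1]], NA_integer_)
    } else {
      for (bn in bnds) {
        tp <- suppressWarnings(as.integer(xml2::xml_attr(bn, "Type")))
        if (is.na(tp) || !(tp %in% 1:3))
          stop("validation error at /ParameterSet/Element[@Symbol='", sym,
               "']/Bond: Type must be 1, 2 or 3")
        rows[[length(rows) + 1L]] <- grab(bn, tp)
      }
    }
  }
  if (!length(rows)) stop("validation error at /ParameterSet: no <Element> entries")
  entries <- do.call(rbind, rows)
  key <- paste(entries$element, entries$mult)
  if (anyDuplicated(key)) {
    d <- entries[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate entry for element ", d$element,
         if (!is.na(d$mult)) paste0(" (bond type ", d$mult, ")") else "")
  }
  eem_parameter_set(name, kappa, entries, provenance = prov)
}

#' Save an EEM parameter set to the XML template
#'
#' Inverse of [load_parameter_set_xml()]; numeric values are written with
#' full precision (17 significant digits) so a load/save/load round-trip
#' is exact.
#'
#' @param set an [eem_parameter_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_parameter_set_xml <- function(set, path) {
  stopifnot(inherits(set, "eem_params"))
  num <- function(v) sprintf("%.17g", v)
  doc <- xml2::xml_new_root("ParameterSet", Name = set$name,
                            Kappa = num(set$kappa),
                            Provenance = set$provenance)
  for (sym in unique(set$entries$element)) {
    sub <- set$entries[set$entries$element == sym, , drop = FALSE]
    el <- xml2::xml_add_child(doc, "Element", Symbol = sym)
    if (all(is.na(sub$mult))) {
      xml2::xml_add_child(el, "Parameters", A = num(sub$A), B = num(sub$B))
    } else {
      for (k in seq_len(nrow(sub)))
        xml2::xml_add_child(el, "Bond", Type = as.character(sub$mult[k]),
                            A = num(sub$A[k]), B = num(sub$B[k]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Duplicate parameters from one element to another
#'
#' Copies every entry of `from_element` (at every multiplicity) to
#' `to_element`, e.g. to give deuterium the parameters of hydrogen when a
#' structure contains D atoms a published set does not cover. Existing
#' entries for `to_element` are overwritten with a warning.
#'
#' @param set an [eem_parameter_set()].
#' @param from_element source element symbol (must be parameterized).
#' @param to_element target element symbol.
#' @return a new [eem_parameter_set()].
#' @export
derive_alias <- function(set, from_element, to_element) {
  stopifnot(inherits(set, "eem_params"))
  src <- set$entries[set$entries$element == from_element, , drop = FALSE]
  if (!nrow(src))
    stop("missing parameter: element ", from_element, " is not in set '",
         set$name, "'")
  if (from_element == to_element) return(set)
  entries <- set$entries
  if (any(entries$element == to_element)) {
    warning("overwriting existing parameters for element ", to_element)
    entries <- entries[entries$element != to_element, , drop = FALSE]
  }
  src$element <- to_element
  eem_parameter_set(set$name, set$kappa, rbind(entries, src),
                    provenance = set$provenance)
}

# atom-type keys occurring in a molecule at the granularity of `set`
molecule_type_keys <- function(set, mol) {
  if (n_atoms(mol) == 0L)
    return(data.frame(element = character(), mult = integer()))
  if (!uses_multiplicity(set))
    return(data.frame(element = unique(mol$atoms$element), mult = NA_integer_))
  mult <- atom_multiplicities(mol)
  if (is.null(mult))
    stop("parameter set '", set$name, "' is bond-order aware, but the ",
         "molecule carries no bond information (PDB/PQR input); use an ",
         "element-granularity set")
  unique(data.frame(element = mol$atoms$element, mult = mult))
}

#' Check whether a parameter set covers a molecule
#'
#' The applicability domain of an EEM parameter set is limited to the atom
#' types it was fitted for; this reports which atom types of the molecule
#' are covered and which are missing.
#'
#' @param set an [eem_parameter_set()].
#' @param mol an [eem_molecule()].
#' @return list with `covered` and `missing` (data.frames of atom-type
#'   keys) and the logical `applicable` (no missing types). An empty
#'   molecule is vacuously applicable.
#' @export
check_applicability <- function(set, mol) {
  keys <- molecule_type_keys(set, mol)
  have <- paste(set$entries$element, set$entries$mult)
  miss <- !(paste(keys$element, keys$mult) %in% have)
  list(covered = keys[!miss, , drop = FALSE],
       missing = keys[miss, , drop = FALSE],
       applicable = !any(miss))
}

#' Select a default parameter set for a molecule
#'
#' Walks the registry in order and returns the first set whose
#' applicability report covers every atom type of the molecule. When no
#' set is fully applicable, the set with the fewest missing atom types is
#' returned (ties broken by registry order) with a warning.
#'
#' @param mol an [eem_molecule()].
#' @param registry list of [eem_parameter_set()] objects, in preference
#'   order; defaults to the built-in registry.
#' @return an [eem_parameter_set()].
#' @export
select_default_set <- function(mol, registry = builtin_parameter_sets()) {
  if (!length(registry)) stop("empty parameter-set registry")
  n_missing <- integer(length(registry))
  for (k in seq_along(registry)) {
    rep <- check_applicability(registry[[k]], mol)
    if (rep$applicable) return(registry[[k]])
    n_missing[k] <- nrow(rep$missing)
  }
  best <- which.min(n_missing)
  warning("no parameter set in the registry covers the molecule; using '",
          registry[[best]]$name, "' (", n_missing[best],
          " atom type(s) unparameterized)")
  registry[[best]]
}

# registry order: documented and stable; names listed here decide preference
.BUILTIN_SET_ORDER <- c("synthetic_protein_elem", "synthetic_organic_elem",
                        "synthetic_organic_bonds")

#' Built-in parameter-set registry
#'
#' Returns the parameter sets shipped with the package, in the documented
#' stable preference order used by [select_default_set()]. The shipped
#' sets are synthetic: their A/B/kappa values were generated once in the
#' ranges typical of published protein-applicable sets (see the package
#' vignette) and are intended for testing and demonstration, not for
#' production charge calculations — load a published set via
#' [load_parameter_set_xml()] for real work.
#'
#' @param order character vector of set names overriding the default
#'   registry order.
#' @return named list of [eem_parameter_set()] objects.
#' @export
builtin_parameter_sets <- function(order = .BUILTIN_SET_ORDER) {
  dir <- system.file("extdata", "parameter-sets", package = "eemkit")
  sets <- lapply(order, function(nm) {
    load_parameter_set_xml(file.path(dir, paste0(nm, ".xml")))
  })
  names(sets) <- order
  sets
}

# per-atom A and B vectors for a molecule under a parameter set, or an
# applicability error listing the missing atom types
atom_parameters <- function(set, mol) {
  rep <- check_applicability(set, mol)
  if (!rep$applicable)
    stop("parameter set '", set$name, "' is not applicable: missing atom type(s) ",
         paste(ifelse(is.na(rep$missing$mult), rep$missing$element,
                      paste0(rep$missing$element, "(", rep$missing$mult, ")")),
               collapse = ", "))
  if (uses_multiplicity(set)) {
    mult <- atom_multiplicities(mol)
    idx <- match(paste(mol$atoms$element, mult),
                 paste(set$entries$element, set$entries$mult))
  } else {
    idx <- match(mol$atoms$element, set$entries$element)
  }
  list(A = set$entries$A[idx], B = set$entries$B[idx])
}
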