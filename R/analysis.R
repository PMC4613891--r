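# Charge analysis: residue/group aggregation, descriptive statistics per
# element / residue type / whole set, and pairwise comparison of charge sets
# (squared Pearson, Spearman, RMSD, sum of absolute differences).

#' Sum atomic charges per residue
#'
#' @param mol an [eem_molecule()].
#' @param charges a [charge_set()] or numeric vector, one value per atom.
#' @return a `residue_charge_set`: a data.frame with the residue identity
#'   columns (`chain`, `resnum`, `icode`, `resname`) and the summed
#'   `charge`, in molecule residue order. The column sums conserve the
#'   total charge of the source set exactly (up to summation tolerance).
#' @export
residue_charges <- function(mol, charges) {
  stopifnot(inherits(mol, "eem_molecule"))
  q <- charge_values(charges)
  if (length(q) != n_atoms(mol))
    stop("dimension error: ", length(q), " charges for ", n_atoms(mol), " atoms")
  sums <- rep(0, nrow(mol$residues))
  agg <- tapply(q, mol$atoms$resid, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  out <- cbind(mol$residues, charge = sums)
  rownames(out) <- NULL
  class(out) <- c("residue_charge_set", "data.frame")
  out
}

#' Sum residue charges over a selection
#'
#' Totals the charge of the residues matching a predicate — e.g. chain
#' membership to get subunit or ring charges in a large complex.
#'
#' @param rcs a `residue_charge_set` from [residue_charges()].
#' @param selection a logical vector over residues, or a predicate
#'   function receiving the residue table and returning one; `NULL`
#'   selects everything.
#' @return the summed charge (0 for an empty selection).
#' @export
group_charge <- function(rcs, selection = NULL) {
  stopifnot(inherits(rcs, "residue_charge_set"))
  keep <- if (is.null(selection)) rep(TRUE, nrow(rcs))
          else if (is.function(selection)) selection(rcs)
          else as.logical(selection)
  if (length(keep) != nrow(rcs))
    stop("selection length does not match the residue count")
  sum(rcs$charge[keep])
}

population_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Descriptive statistics of a charge set
#'
#' Count, min, max, average, median and standard deviation per group. The
#' standard deviation is the population form (divide by n): the values
#' describe a complete set of atoms, not a sample. The median of an
#' even-sized group is the midpoint of the two central values.
#'
#' @param charges a [charge_set()], `residue_charge_set`, or numeric
#'   vector.
#' @param group_by `"none"` (one row for the whole set), `"element"`, or
#'   `"residue_name"`.
#' @param mol the source [eem_molecule()]; required for `"element"` (and
#'   for `"residue_name"` on atomic charge sets).
#' @return data.frame with columns `group`, `count`, `min`, `max`,
#'   `average`, `median`, `stddev`; group counts sum to the input length.
#' @export
charge_statistics <- function(charges, group_by = c("none", "element", "residue_name"),
                              mol = NULL) {
  group_by <- match.arg(group_by)
  v <- charge_values(charges)
  if (!length(v)) stop("empty input: no charges to summarize")
  groups <- switch(group_by,
    none = rep("all", length(v)),
    element = {
      if (inherits(charges, "residue_charge_set"))
        stop("element grouping applies to atomic charges")
      if (is.null(mol)) stop("grouping by element requires `mol`")
      if (n_atoms(mol) != length(v)) stop("dimension error: charges vs molecule")
      mol$atoms$element
    },
    residue_name = {
      if (inherits(charges, "residue_charge_set")) charges$resname
      else {
        if (is.null(mol)) stop("grouping by residue name requires `mol`")
        if (n_atoms(mol) != length(v)) stop("dimension error: charges vs molecule")
        mol$residues$resname[mol$atoms$resid]
      }
    })
  out <- do.call(rbind, lapply(split(v, groups), function(g) {
    data.frame(count = length(g), min = min(g), max = max(g),
               average = mean(g), median = stats::median(g),
               stddev = population_sd(g))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Compare two charge sets
#'
#' Pairwise comparison indicators between charge sets of the same kind
#' and length: squared Pearson correlation, Spearman rank correlation
#' (average ranks on ties), RMSD and the sum of absolute differences.
#' When either vector has zero variance the correlations are undefined
#' and reported as `NA` with `undefined_correlation = TRUE` — not as 0,
#' which would fake (dis)agreement for constant sets.
#'
#' @param a,b charge sets ([charge_set()], `residue_charge_set`, or
#'   numeric vectors) of equal length >= 2.
#' @return list of class `charge_comparison` with `r_squared`,
#'   `spearman`, `rmsd`, `sum_abs_diff`, `n` and `undefined_correlation`.
#' @export
compare_charge_sets <- function(a, b) {
  if (inherits(a, "residue_charge_set") != inherits(b, "residue_charge_set"))
    stop("cannot compare atomic charges with residue charges")
  va <- charge_values(a); vb <- charge_values(b)
  if (length(va) != length(vb))
    stop("dimension error: lengths ", length(va), " and ", length(vb))
  if (length(va) < 2L) stop("need at least 2 values to compare")
  degenerate <- population_sd(va) == 0 || population_sd(vb) == 0
  structure(list(
    r_squared = if (degenerate) NA_real_ else stats::cor(va, vb)^2,
    spearman = if (degenerate) NA_real_ else stats::cor(va, vb, method = "spearman"),
    rmsd = sqrt(mean((va - vb)^2)),
    sum_abs_diff = sum(abs(va - vb)),
    n = length(va),
    undefined_correlation = degenerate), class = "charge_comparison")
}

#' @export
print.charge_comparison <- function(x, ...) {
  cat("charge comparison over", x$n, "values:\n",
      " R^2 =", format(x$r_squared, digits = 6),
      " Spearman =", format(x$spearman, digits = 6), "\n",
      " RMSD =", format(x$rmsd, digits = 6), "e",
      " sum|diff| =", format(x$sum_abs_diff, digits = 6), "e\n")
  if (x$undefined_correlation)
    cat("  (correlations undefined: a compared set has zero variance)\n")
  invisible(x)
}

#' @export
as.data.frame.charge_comparison <- function(x, ...) {
  data.frame(r_squared = x$r_squared, spearman = x$spearman, rmsd = x$rmsd,
             sum_abs_diff = x$sum_abs_diff, n = x$n,
             undefined_correlation = x$undefined_correlation)
}
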