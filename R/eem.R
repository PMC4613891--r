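# Full EEM: assemble and solve the dense (N+1) x (N+1) electronegativity
# equalization system. For each atom i,
#
#     B_i q_i + kappa * sum_{j != i} q_j / R_ij - chi_bar = -A_i
#
# with the total-charge constraint sum_i q_i = Q as the last row and the
# equalized molecular electronegativity chi_bar as the (N+1)-th unknown.
# Distances are in Angstrom; charges in units of e. The solve is a direct
# dense factorization (LAPACK), O(N^3) time and O(N^2) space.

#' Construct a charge set
#'
#' One partial charge per atom (units of e), tagged with the job that
#' produced it and with the equalized molecular electronegativity solved
#' alongside the charges.
#'
#' @param values numeric vector of per-atom charges.
#' @param chi_bar equalized electronegativity (may be `NA` for charge sets
#'   read from files).
#' @param job list describing the producing job: `method` ("full",
#'   "cutoff", "cover", or "file"), `parameter_set`, `radius`, `precision`,
#'   `total_charge`, plus method-specific extras.
#' @return an object of class `charge_set`.
#' @export
charge_set <- function(values, chi_bar = NA_real_, job = list(method = "file")) {
  stopifnot(is.numeric(values))
  structure(list(values = as.numeric(values), chi_bar = chi_bar, job = job),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("charge_set:", length(x$values), "atoms, method =", x$job$method,
      "\n  sum(q) =", format(sum(x$values), digits = 8),
      " chi_bar =", format(x$chi_bar, digits = 6), "\n")
  invisible(x)
}

# numeric charge vector out of a charge_set / residue_charge_set / vector
charge_values <- function(x) {
  if (inherits(x, "charge_set")) x$values
  else if (inherits(x, "residue_charge_set")) x$charge
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a charge_set, residue_charge_set or numeric vector")
}

check_geometry <- function(mol) {
  if (n_atoms(mol) == 0L)
    stop("empty molecule: nothing to solve (did stripping waters remove every atom?)")
}

#' Build the full EEM system for a molecule
#'
#' Returns the dense augmented matrix and right-hand side explicitly,
#' mainly for inspection and verification; [solve_full_eem()] assembles
#' the same system in compiled code without materializing it in R. Memory
#' is Theta(N^2) — intended for small to medium systems.
#'
#' @param mol an [eem_molecule()].
#' @param params an [eem_parameter_set()] applicable to `mol`.
#' @param total_charge total molecular charge Q in units of e; defaults to
#'   the molecule's `total_charge`.
#' @return list with `matrix` ((N+1) x (N+1)), `rhs` (length N+1),
#'   `atom_order` (rows 1..N map to atom indices) and `precision`.
#' @export
build_eem_system <- function(mol, params, total_charge = mol$total_charge) {
  stopifnot(inherits(mol, "eem_molecule"), inherits(params, "eem_params"))
  check_geometry(mol)
  ab <- atom_parameters(params, mol)
  n <- n_atoms(mol)
  X <- coords(mol)
  M <- matrix(0, n + 1L, n + 1L)
  if (n > 1L) {
    D <- as.matrix(stats::dist(X))
    close <- which(D < 1e-4 & upper.tri(D), arr.ind = TRUE)
    if (nrow(close))
      stop("degenerate geometry: atoms ", close[1, 1], " and ", close[1, 2],
           " are closer than 1e-4 Angstrom")
    M[1:n, 1:n] <- params$kappa / D
  }
  diag(M)[1:n] <- ab$B
  M[1:n, n + 1L] <- -1
  M[n + 1L, 1:n] <- 1
  rhs <- c(-ab$A, total_charge)
  list(matrix = M, rhs = rhs, atom_order = seq_len(n), precision = 64L)
}

#' Solve the full EEM system
#'
#' Direct dense solve of the complete electronegativity-equalization
#' system: all N charges and the equalized electronegativity are obtained
#' at once, and the charges sum to the total molecular charge to solver
#' tolerance (1e-6 e at 64-bit precision). In 32-bit mode both assembly
#' and factorization run in single precision, halving memory at the cost
#' of accuracy; results are returned in doubles.
#'
#' @inheritParams build_eem_system
#' @param precision 64 (default) or 32.
#' @return a [charge_set()] with job method `"full"`.
#' @export
solve_full_eem <- function(mol, params, total_charge = mol$total_charge,
                           precision = 64L) {
  stopifnot(inherits(mol, "eem_molecule"), inherits(params, "eem_params"))
  precision <- match.arg(as.character(precision), c("64", "32"))
  check_geometry(mol)
  ab <- atom_parameters(params, mol)
  res <- cpp_solve_full(coords(mol), ab$A, ab$B, params$kappa,
                        as.numeric(total_charge), precision == "32")
  charge_set(res$q, chi_bar = res$chi_bar,
             job = list(method = "full", parameter_set = params$name,
                        radius = NA_real_, precision = as.integer(precision),
                        total_charge = as.numeric(total_charge)))
}
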