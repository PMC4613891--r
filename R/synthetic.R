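# Synthetic fixtures: seeded generators for globular and chain point-cloud
# molecules at protein-like density, random (well-conditioned) parameter
# sets, and QSPR datasets — plus the deliberately naive full-EEM oracle used
# to verify the production solver. Generated molecules carry no bonds and
# exercise element-granularity parameter sets, which is what PDB-derived
# systems provide.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random globular molecule
#'
#' Uniform random points in a sphere whose radius follows from the
#' requested density, `(3 n / (4 pi density))^(1/3)`, rejection-sampled on
#' a cell grid so that no two atoms come closer than `min_separation`.
#' Elements are drawn from `element_freqs`; atoms are grouped into
#' pseudo-residues of 10 so residue-level operations have deterministic
#' structure. Deterministic under `seed`.
#'
#' @param n_atoms number of atoms.
#' @param density atoms per cubic Angstrom; 0.1 is protein-like.
#' @param min_separation minimum pairwise distance in Angstrom.
#' @param element_freqs named element probabilities.
#' @param seed integer seed.
#' @return an [eem_molecule()].
#' @export
generate_globule <- function(n_atoms, density = 0.1, min_separation = 1.0,
                             element_freqs = c(H = 0.5, C = 0.3, N = 0.1, O = 0.1),
                             seed = 1L) {
  stopifnot(n_atoms >= 1L, density > 0, min_separation > 0)
  R <- (3 * n_atoms / (4 * pi * density))^(1 / 3)
  # feasibility guard: random sequential packing stalls near fraction ~0.3
  if (density * (pi / 6) * min_separation^3 > 0.3)
    stop("packing error: min_separation ", min_separation,
         " is infeasible at density ", density)
  with_seed(seed, {
    X <- matrix(0, n_atoms, 3)
    edge <- min_separation
    grid <- new.env(hash = TRUE, parent = emptyenv())
    cell_key <- function(p) paste(floor(p / edge), collapse = " ")
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n_atoms
    while (placed < n_atoms) {
      if (attempts >= max_attempts)
        stop("packing error: could not place ", n_atoms, " atoms at density ",
             density, " with min_separation ", min_separation)
      attempts <- attempts + 1L
      # uniform point in the sphere by radius inversion
      u <- stats::runif(1)
      r <- R * u^(1 / 3)
      v <- stats::rnorm(3)
      p <- r * v / sqrt(sum(v^2))
      cc <- floor(p / edge)
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        key <- paste(cc[1] + dx, cc[2] + dy, cc[3] + dz)
        idxs <- grid[[key]]
        if (!is.null(idxs)) {
          d2 <- colSums((t(X[idxs, , drop = FALSE]) - p)^2)
          if (any(d2 < min_separation^2)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      placed <- placed + 1L
      X[placed, ] <- p
      key <- cell_key(p)
      grid[[key]] <- c(grid[[key]], placed)
    }
    elements <- sample(names(element_freqs), n_atoms, replace = TRUE,
                       prob = element_freqs)
    build_pointcloud_molecule(X, elements, residue_size = 10L,
                              source_tag = "generated globule")
  })
}

#' Generate a collinear chain molecule
#'
#' Atoms on the x axis at uniform spacing; handy for analytic
#' neighbor-count and fragment checks. A 2-atom chain is the diatomic of
#' the closed-form EEM solution.
#'
#' @param n_atoms number of atoms.
#' @param spacing inter-atom spacing in Angstrom (> 0).
#' @param element element symbol for every atom, or a vector of symbols.
#' @return an [eem_molecule()].
#' @export
generate_chain <- function(n_atoms, spacing, element = "C") {
  stopifnot(n_atoms >= 1L, spacing > 0)
  X <- cbind(x = (seq_len(n_atoms) - 1L) * spacing, y = 0, z = 0)
  build_pointcloud_molecule(X, rep_len(element, n_atoms), residue_size = 10L,
                            source_tag = "generated chain")
}

build_pointcloud_molecule <- function(X, elements, residue_size, source_tag) {
  n <- nrow(X)
  resid <- ((seq_len(n) - 1L) %/% residue_size) + 1L
  residues <- data.frame(chain = "A", resnum = seq_len(max(resid)),
                         icode = "", resname = "SYN",
                         stringsAsFactors = FALSE)
  atoms <- data.frame(element = elements,
                      name = paste0(elements, seq_len(n)),
                      x = X[, 1], y = X[, 2], z = X[, 3], resid = resid,
                      serial = seq_len(n), altloc = "", occupancy = 1,
                      stringsAsFactors = FALSE)
  eem_molecule(atoms, residues, total_charge = 0L,
               source = c(file = source_tag, format = "generated"))
}

#' Generate a random protein-like parameter set
#'
#' Element-granularity parameters drawn uniformly: A in \[2, 8\], B in
#' \[6, 14\], kappa in \[0.3, 0.6\]. The ranges mimic published
#' protein-applicable sets and keep the EEM systems well-conditioned.
#'
#' @param elements element symbols to parameterize.
#' @param seed integer seed.
#' @return an [eem_parameter_set()].
#' @export
generate_parameter_set <- function(elements, seed = 1L) {
  stopifnot(length(elements) >= 1L)
  with_seed(seed, {
    entries <- data.frame(element = elements, mult = NA_integer_,
                          A = stats::runif(length(elements), 2, 8),
                          B = stats::runif(length(elements), 6, 14))
    eem_parameter_set(paste0("generated_seed", seed),
                      kappa = stats::runif(1, 0.3, 0.6), entries,
                      provenance = "seeded synthetic set for testing")
  })
}

#' Naive full-EEM oracle
#'
#' Independent verification path for [solve_full_eem()]: builds the EEM
#' matrix with explicit R loops (sharing no code with the production
#' assembly) and solves it by textbook Gaussian elimination with partial
#' pivoting. Deliberately restricted to N <= 200.
#'
#' @inheritParams solve_full_eem
#' @return a [charge_set()] with job method `"oracle"`.
#' @export
oracle_full_solve <- function(mol, params, total_charge = mol$total_charge) {
  stopifnot(inherits(mol, "eem_molecule"), n_atoms(mol) <= 200L)
  ab <- atom_parameters(params, mol)
  n <- n_atoms(mol)
  at <- mol$atoms
  M <- matrix(0, n + 1, n + 1)
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    M[i, i] <- ab$B[i]
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      M[i, j] <- params$kappa / r
    }
    M[i, n + 1] <- -1
    M[n + 1, i] <- 1
    b[i] <- -ab$A[i]
  }
  b[n + 1] <- total_charge

  # Gaussian elimination with partial pivoting
  m <- n + 1
  for (col in seq_len(m - 1)) {
    piv <- which.max(abs(M[col:m, col])) + col - 1L
    if (abs(M[piv, col]) < .Machine$double.eps * m)
      stop("oracle-singular error: zero pivot in column ", col)
    if (piv != col) {
      M[c(col, piv), ] <- M[c(piv, col), ]
      b[c(col, piv)] <- b[c(piv, col)]
    }
    for (row in (col + 1):m) {
      f <- M[row, col] / M[col, col]
      if (f != 0) {
        M[row, ] <- M[row, ] - f * M[col, ]
        b[row] <- b[row] - f * b[col]
      }
    }
  }
  x <- numeric(m)
  for (row in m:1) {
    x[row] <- (b[row] - sum(M[row, -seq_len(row)] * x[-seq_len(row)])) / M[row, row]
  }
  charge_set(x[seq_len(n)], chi_bar = x[m],
             job = list(method = "oracle", parameter_set = params$name,
                        radius = NA_real_, precision = 64L,
                        total_charge = as.numeric(total_charge)))
}

#' Generate a synthetic QSPR dataset
#'
#' Descriptors drawn uniformly in \[-1, 1\] (magnitudes typical of
#' carboxyl-atom charges) and observations generated from `true_model`
#' plus Gaussian noise. Deterministic under `seed`.
#'
#' @param true_model the generating [qspr_model()].
#' @param n number of molecules.
#' @param noise_sigma standard deviation of the observation noise (pKa
#'   units).
#' @param seed integer seed.
#' @return list with `descriptors` (data.frame) and `observed_pka`.
#' @export
generate_qspr_dataset <- function(true_model, n, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(true_model, "qspr_model"), n >= 1L)
  with_seed(seed, {
    p <- length(true_model$descriptor_names)
    X <- matrix(stats::runif(n * p, -1, 1), n, p,
                dimnames = list(NULL, true_model$descriptor_names))
    X <- as.data.frame(X)
    pka <- apply(X, 1L, function(row) predict_pka(true_model, row)) +
      stats::rnorm(n, 0, noise_sigma)
    list(descriptors = X, observed_pka = as.numeric(pka))
  })
}

#' Write a molecule as a PDB file
#'
#' Lets generated fixtures exercise the structure I/O end-to-end.
#'
#' @param mol an [eem_molecule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "eem_molecule"))
  at <- mol$atoms
  res <- mol$residues[at$resid, , drop = FALSE]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = res$resnum, resid = res$resname,
                   eleno = seq_len(n_atoms(mol)), elety = at$name,
                   chain = ifelse(nzchar(res$chain), res$chain, "A"),
                   elesy = toupper(at$element))
  invisible(path)
}
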