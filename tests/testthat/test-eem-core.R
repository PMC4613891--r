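# Full EEM system construction and solution.

test_that("the assembled system matches the EEM equations entry by entry", {
  # homonuclear diatomic, R = 1.5, kappa = 0.5, A = 2, B = 8
  mol <- generate_chain(2, spacing = 1.5)
  ps <- eem_parameter_set("t", 0.5,
                          data.frame(element = "C", mult = NA, A = 2, B = 8))
  sys <- build_eem_system(mol, ps, 0)
  expect_equal(dim(sys$matrix), c(3L, 3L))
  expect_equal(diag(sys$matrix), c(8, 8, 0))
  expect_equal(sys$matrix[1, 2], 0.5 / 1.5)
  expect_equal(sys$matrix[2, 1], 0.5 / 1.5)
  expect_equal(sys$matrix[1:2, 3], c(-1, -1))
  expect_equal(sys$matrix[3, 1:2], c(1, 1))
  expect_equal(sys$rhs, c(-2, -2, 0))

  # 5-atom chain vs an independently hand-built matrix
  mol5 <- generate_chain(5, spacing = 1.3)
  mol5$atoms$element <- c("C", "N", "O", "H", "C")
  ps5 <- fixture_params()
  sys5 <- build_eem_system(mol5, ps5, 1)
  ab <- eemkit:::atom_parameters(ps5, mol5)
  M <- matrix(0, 6, 6)
  for (i in 1:5) for (j in 1:5)
    M[i, j] <- if (i == j) ab$B[i] else ps5$kappa / (1.3 * abs(i - j))
  M[1:5, 6] <- -1; M[6, 1:5] <- 1
  expect_equal(sys5$matrix, M)
  expect_equal(sys5$rhs, c(-ab$A, 1))
})

test_that("a single atom takes the whole molecular charge", {
  mol <- generate_chain(1, spacing = 1)
  ps <- fixture_params(c("C"))
  sys <- build_eem_system(mol, ps, -2)
  expect_equal(dim(sys$matrix), c(2L, 2L))
  for (Q in c(-2L, 0L, 3L)) {
    cs <- solve_full_eem(mol, ps, Q)
    expect_equal(cs$values, Q)
  }
})

test_that("symmetric diatomics split the charge evenly", {
  mol <- generate_chain(2, spacing = 1.5)
  ps <- eem_parameter_set("t", 0.5,
                          data.frame(element = "C", mult = NA, A = 2, B = 8))
  expect_equal(solve_full_eem(mol, ps, 0)$values, c(0, 0))
  expect_equal(solve_full_eem(mol, ps, 1)$values, c(0.5, 0.5))
})

test_that("the diatomic closed form holds across random parameter draws", {
  # q1 = (A2 - A1) / (B1 + B2 - 2 kappa / R), Q = 0
  mol <- fixture_diatomic(1)
  cs <- solve_full_eem(mol, eem_parameter_set("d", 1,
          data.frame(element = c("C", "N"), mult = NA, A = c(2, 6), B = c(8, 8))), 0)
  expect_equal(cs$values, c(4 / 14, -4 / 14), tolerance = 1e-12)

  set.seed(42)
  for (k in 1:300) {
    A <- runif(2, 1, 8); B <- runif(2, 5, 15)
    kap <- runif(1, 0.3, 1); R <- runif(1, 0.8, 3)
    if (abs(B[1] + B[2] - 2 * kap / R) < 1e-3) next
    ps <- eem_parameter_set("d", kap,
            data.frame(element = c("C", "N"), mult = NA, A = A, B = B))
    q1 <- (A[2] - A[1]) / (B[1] + B[2] - 2 * kap / R)
    got <- solve_full_eem(fixture_diatomic(R), ps, 0)$values
    expect_equal(got, c(q1, -q1), tolerance = 1e-9)
  }
})

test_that("charges conserve the total molecular charge", {
  for (seed in 1:5) {
    mol <- generate_globule(80, seed = seed)
    ps <- generate_parameter_set(c("H", "C", "N", "O"), seed = seed + 100)
    for (Q in c(-3L, 0L, 7L)) {
      cs <- solve_full_eem(mol, ps, Q)
      expect_lt(abs(sum(cs$values) - Q), 1e-6)
    }
  }
})

test_that("charges are invariant under rigid motion and equivariant under permutation", {
  mol <- generate_globule(60, seed = 9)
  ps <- generate_parameter_set(c("H", "C", "N", "O"), seed = 9)
  ref <- solve_full_eem(mol, ps, 1)

  # rotation (about z by 0.7 rad) plus translation
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- mol
  XY <- coords(mol) %*% Rz
  moved$atoms$x <- XY[, 1] + 13.7
  moved$atoms$y <- XY[, 2] - 5.1
  moved$atoms$z <- XY[, 3] + 0.9
  expect_charge_equal(solve_full_eem(moved, ps, 1), ref, 1e-9)

  # permutation of atom order permutes charges identically
  set.seed(1)
  perm <- sample(n_atoms(mol))
  pmol <- mol
  pmol$atoms <- mol$atoms[perm, ]
  pmol$atoms$resid <- mol$atoms$resid[perm]
  rownames(pmol$atoms) <- NULL
  got <- solve_full_eem(pmol, ps, 1)$values
  expect_equal(got, ref$values[perm], tolerance = 1e-10)
})

test_that("chemically and geometrically equivalent atoms get equal charges", {
  # square of four identical atoms: all equivalent
  sq <- generate_chain(4, spacing = 1)
  sq$atoms$x <- c(0, 2, 2, 0); sq$atoms$y <- c(0, 0, 2, 2)
  ps <- fixture_params(c("C"))
  q <- solve_full_eem(sq, ps, 1)$values
  expect_lt(max(q) - min(q), 1e-8)
  # mirror-equivalent pair in a heteronuclear linear O-C-O arrangement
  oco <- generate_chain(3, spacing = 1.2)
  oco$atoms$element <- c("O", "C", "O")
  q2 <- solve_full_eem(oco, fixture_params(), 0)$values
  expect_equal(q2[1], q2[3], tolerance = 1e-10)
})

test_that("solver agrees with the naive elimination oracle", {
  for (seed in 1:10) {
    n <- 10 + 4 * seed
    mol <- generate_globule(n, seed = seed)
    ps <- generate_parameter_set(c("H", "C", "N", "O"), seed = seed + 50)
    Q <- (seed %% 3) - 1
    fast <- solve_full_eem(mol, ps, Q)
    slow <- oracle_full_solve(mol, ps, Q)
    expect_charge_equal(fast, slow, 1e-9)
    expect_equal(fast$chi_bar, slow$chi_bar, tolerance = 1e-8)
  }
})

test_that("32-bit precision mode reproduces 64-bit charges to single accuracy", {
  mol <- generate_globule(120, seed = 4)
  ps <- generate_parameter_set(c("H", "C", "N", "O"), seed = 4)
  q64 <- solve_full_eem(mol, ps, 0, precision = 64)
  q32 <- solve_full_eem(mol, ps, 0, precision = 32)
  expect_charge_equal(q64, q32, 1e-3)
  expect_gt(max(abs(q64$values - q32$values)), 0)  # genuinely lower precision
})

test_that("degenerate geometry and inapplicable parameters are rejected", {
  dup <- generate_chain(3, spacing = 1)
  dup$atoms$x[3] <- dup$atoms$x[1] + 5e-5
  dup$atoms$y[3] <- 0
  ps <- fixture_params(c("C"))
  expect_error(solve_full_eem(dup, ps, 0), "degenerate geometry")
  expect_error(build_eem_system(dup, ps, 0), "degenerate geometry")
  mol <- fixture_diatomic(1.2, c("C", "Zn"))
  expect_error(solve_full_eem(mol, fixture_params(), 0), "not applicable")
})
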