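test_that("pKa prediction is the linear model it claims to be", {
  flat <- qspr_model(c("q_HO4", "q_O4", "q_C4"), c(0, 0, 0), 4.2)
  expect_equal(predict_pka(flat, c(q_HO4 = 0.3, q_O4 = -0.4, q_C4 = 0.1)), 4.2)
  cancel <- qspr_model(c("a", "b"), c(1, -1), 0)
  expect_equal(predict_pka(cancel, c(a = 0.3, b = 0.3)), 0)
  expect_error(predict_pka(cancel, c(a = 0.3)), "missing descriptor.*b")
  # linearity: doubling a descriptor's deviation doubles its contribution
  m <- qspr_model(c("x", "y"), c(2.5, -1.5), 1)
  base <- predict_pka(m, c(x = 0.1, y = 0.2))
  up1 <- predict_pka(m, c(x = 0.2, y = 0.2))
  up2 <- predict_pka(m, c(x = 0.3, y = 0.2))
  expect_equal(up2 - base, 2 * (up1 - base), tolerance = 1e-12)
})

test_that("QSPR models round-trip through JSON, including the shipped example", {
  m <- qspr_model(c("q_H", "q_O1"), c(-12.5, 3.25), 7.125, name = "rt")
  path <- tempfile(fileext = ".json")
  save_qspr_model(m, path)
  back <- load_qspr_model(path)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$descriptor_names, m$descriptor_names)

  shipped <- load_qspr_model(system.file("extdata", "qspr-models",
                                         "synthetic_phenol.json",
                                         package = "eemkit"))
  expect_equal(shipped$descriptor_names, c("q_HO4", "q_O4", "q_C4"))
  expect_length(shipped$coefficients, 3L)
})

test_that("descriptor extraction binds charges by atom name", {
  mol <- generate_chain(3, spacing = 1.2)
  mol$atoms$element <- c("O", "C", "H")
  mol$atoms$name <- c("O4", "C4", "HO4")
  cs <- charge_set(c(-0.5, 0.2, 0.3))
  d <- extract_descriptors(mol, cs, c(q_HO4 = "HO4", q_O4 = "O4", q_C4 = "C4"))
  expect_equal(d, c(q_HO4 = 0.3, q_O4 = -0.5, q_C4 = 0.2))
  expect_error(extract_descriptors(mol, cs, c(q_X = "XX9")), "not found")
})

test_that("dissociation removes the acidic H and decrements the total charge", {
  mol <- generate_chain(4, spacing = 1.1)
  mol$atoms$element <- c("C", "O", "O", "H")
  mol$atoms$name <- c("C1", "O1", "O2", "H")
  anion <- make_dissociated(mol, 4L)
  expect_equal(n_atoms(anion), 3L)
  expect_equal(anion$total_charge, -1L)
  by_name <- make_dissociated(mol, "H")
  expect_equal(coords(by_name), coords(anion))
  expect_error(make_dissociated(mol, 1L), "invalid deprotonation")
  # conservation chain: the solved anion sums to -1
  ps <- fixture_params(c("C", "O"))
  cs <- solve_full_eem(anion, ps)
  expect_lt(abs(sum(cs$values) + 1), 1e-6)
})

test_that("the ionized fraction follows Henderson-Hasselbalch", {
  expect_equal(ionized_fraction(7.0, 7.0), 0.5)
  expect_equal(ionized_fraction(9.36, 2), 10^(2 - 9.36) / (1 + 10^(2 - 9.36)))
  expect_lt(ionized_fraction(9.36, 2), 1e-7)  # unionized at stomach pH
  # strictly increasing in pH with limits 0 and 1
  ph <- seq(-4, 18, by = 0.5)
  f <- ionized_fraction(5, ph)
  expect_true(all(diff(f) > 0))
  expect_lt(f[1], 1e-8)
  expect_gt(f[length(f)], 1 - 1e-8)
})

test_that("multilinear fitting recovers a noise-free generating model exactly", {
  true <- qspr_model(c("q_H", "q_O1", "q_O2"), c(-20, 8, 5), 4.8)
  data <- generate_qspr_dataset(true, n = 30, noise_sigma = 0, seed = 8)
  fit <- fit_qspr(data$descriptors, data$observed_pka)
  expect_equal(fit$coefficients, true$coefficients, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$intercept, true$intercept, tolerance = 1e-8)
})

test_that("noisy fits recover coefficients within sampling error", {
  true <- qspr_model(c("q_H", "q_O1", "q_O2"), c(-20, 8, 5), 4.8)
  data <- generate_qspr_dataset(true, n = 45, noise_sigma = 0.2, seed = 12)
  fit <- fit_qspr(data$descriptors, data$observed_pka)
  X <- cbind(1, as.matrix(data$descriptors))
  se <- sqrt(diag(solve(crossprod(X))) * 0.2^2)
  est <- c(fit$intercept, fit$coefficients)
  expect_true(all(abs(est - c(4.8, -20, 8, 5)) <= 3 * se))
})

test_that("degenerate designs are rejected with named columns", {
  X <- data.frame(a = 1:6 / 10, b = (1:6) / 5)   # b = 2a: collinear
  expect_error(fit_qspr(X, rnorm(6)), "collinear.*b")
  X2 <- data.frame(a = 1:3 / 10, b = c(0.2, 0.1, 0.4), c = c(0.3, 0, 0.1))
  expect_error(fit_qspr(X2, rnorm(3)), "at least")
})

test_that("cross-validation reports per-round and mean errors as configured", {
  true <- qspr_model(c("q_H", "q_O1"), c(-15, 6), 5)
  clean <- generate_qspr_dataset(true, n = 45, noise_sigma = 0, seed = 3)
  cv0 <- cross_validate(clean$descriptors, clean$observed_pka, k = 5,
                        train_size = 35, seed = 2)
  expect_length(cv0$mae, 5L)
  expect_lt(cv0$mean_mae, 1e-8)

  noisy <- generate_qspr_dataset(true, n = 45, noise_sigma = 0.25, seed = 4)
  cv1 <- cross_validate(noisy$descriptors, noisy$observed_pka, k = 1,
                        train_size = 35, seed = 5)
  expect_length(cv1$fold_models, 1L)            # degenerate k is well-formed
  expect_true(is.finite(cv1$mean_mae))

  # reproducible splits under the same seed; each round trains on 35
  cv2 <- cross_validate(noisy$descriptors, noisy$observed_pka, k = 5,
                        train_size = 35, seed = 6)
  cv3 <- cross_validate(noisy$descriptors, noisy$observed_pka, k = 5,
                        train_size = 35, seed = 6)
  expect_identical(cv2$splits, cv3$splits)
  expect_true(all(lengths(cv2$splits) == 35L))

  # disjoint-fold mode partitions the data
  cvf <- cross_validate(noisy$descriptors, noisy$observed_pka, k = 5,
                        seed = 7, mode = "folds")
  held_out <- unlist(lapply(cvf$splits, function(tr) setdiff(1:45, tr)))
  expect_setequal(held_out, 1:45)
  expect_error(cross_validate(noisy$descriptors, noisy$observed_pka,
                              k = 5, train_size = 45, seed = 1),
               "no validation")
})
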