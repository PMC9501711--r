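test_that("the cosine basis evaluates to its closed-form zeros and is periodic", {
  expect_equal(evaluate_torsion(fourier_torsion(1), 180), 0)
  expect_equal(evaluate_torsion(fourier_torsion(c(0, 0, 2)), 60), 0)
  term <- fourier_torsion(c(1.3, -0.4, 2.2, 0.9), offset = 0.5)
  th <- seq(-180, 180, by = 7)
  expect_equal(evaluate_torsion(term, th), evaluate_torsion(term, th + 360),
               tolerance = 1e-12)
})

test_that("residual profiles reduce to the expected limits", {
  mol <- make_toy_ligand("catechol_amine_like")
  truth <- fourier_torsion(c(1.0, 0, 3.0, 0))
  scan <- make_scan(mol, mol$dihedrals$gamma, truth)
  # zero charges and LJ: residual is the QM profile shifted to min 0
  mol0 <- mol
  mol0$atoms$charge <- 0; mol0$atoms$sigma <- 0; mol0$atoms$epsilon <- 0
  scan0 <- make_scan(mol0, mol0$dihedrals$gamma, truth)
  rp0 <- residual_profile(scan0, mol0)
  expect_equal(rp0$energy, scan0$qm_energy - min(scan0$qm_energy),
               tolerance = 1e-10)
  # QM equal to the nonbonded background: residual identically zero
  scan_nb <- scan
  scan_nb$qm_energy <- kcal_to_kj(
    purrr::map_dbl(scan$conf, nonbonded_energy, mol = mol))
  expect_equal(residual_profile(scan_nb, mol)$energy,
               rep(0, nrow(scan_nb)), tolerance = 1e-10)
  # constructed scan: residual recovers the ground-truth torsion shape
  rp <- residual_profile(scan, mol)
  want <- evaluate_torsion(truth, rp$angle)
  expect_equal(rp$energy, want - min(want), tolerance = 1e-9)
})

test_that("least-squares fit recovers exact cosine series", {
  grid24 <- seq(-165, 180, by = 15)
  truth <- fourier_torsion(c(2.1, -1.4, 3.3, 0.8), offset = 1.7)
  prof <- tibble::tibble(angle = grid24, energy = evaluate_torsion(truth, grid24))
  fit <- fit_fourier(prof, 4)
  expect_equal(fit$term$coefficients, truth$coefficients, tolerance = 1e-8)
  expect_lt(glance(fit)$rmse, 1e-8)
  # flat profile: all coefficients zero
  flat <- fit_fourier(tibble::tibble(angle = grid24, energy = 0), 4)
  expect_equal(flat$term$coefficients, rep(0, 4), tolerance = 1e-10)
  expect_equal(flat$term$offset, 0, tolerance = 1e-10)
  # pure V3 fit with N = 4 leaves other orders at zero
  v3 <- tibble::tibble(angle = grid24,
                       energy = evaluate_torsion(fourier_torsion(c(0, 0, 2)), grid24))
  fit3 <- fit_fourier(v3, 4)
  expect_equal(fit3$term$coefficients, c(0, 0, 2, 0), tolerance = 1e-8)
})

test_that("fit reporting: tidy/glance shapes, overrides, weights, conditioning", {
  grid <- seq(-170, 180, by = 10)
  truth <- fourier_torsion(c(1, 2, 3, 4))
  prof <- tibble::tibble(angle = grid, energy = evaluate_torsion(truth, grid))
  fit <- fit_fourier(prof, 4, overrides = c(V3 = 9))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "V3"], 9)
  expect_true(td$overridden[td$term == "V3"])
  expect_false(any(td$overridden[td$term != "V3"]))
  expect_named(glance(fit), c("rmse", "max_abs_residual", "nobs", "max_order"))
  expect_error(fit_fourier(prof, 4, overrides = c(V9 = 1)), "unknown override")
  # Boltzmann weighting is accepted and deterministic
  fw1 <- fit_fourier(prof, 4, boltzmann_temperature = 300)
  fw2 <- fit_fourier(prof, 4, boltzmann_temperature = 300)
  expect_identical(fw1$term, fw2$term)
  # aliasing: on 0/90/180/270 the V3 basis equals the V1 basis
  alias <- tibble::tibble(angle = c(0, 90, 180, -90), energy = c(1, 0, 1, 0))
  expect_error(fit_fourier(alias, 3), "rank-deficient")
  expect_error(fit_fourier(tibble::tibble(angle = 1:3, energy = 0), 4),
               "max_order")
})

test_that("fit RMSE is non-increasing in the basis order", {
  grid <- seq(-175, 180, by = 5)
  withr::with_seed(13, {
    energy <- evaluate_torsion(fourier_torsion(c(1.5, -2, 4, 1)), grid) +
      rnorm(length(grid), sd = 0.6)
    prof <- tibble::tibble(angle = grid, energy = energy)
    rmse <- vapply(1:6, function(N) glance(fit_fourier(prof, N))$rmse, 1)
    expect_true(all(diff(rmse) <= 1e-12))
  })
})

test_that("underfitting a V3 potential leaves the analytic projection residual", {
  # on a uniform full-period grid the cos(3 theta) component is orthogonal
  # to the order-1/2 basis, so the N = 2 fit keeps only the constant and
  # the RMSE is |V3|/2 * RMS(cos 3 theta) = |V3|/(2 sqrt(2))
  grid <- seq(-165, 180, by = 15)
  v3 <- 2
  prof <- tibble::tibble(angle = grid,
                         energy = evaluate_torsion(fourier_torsion(c(0, 0, v3)), grid))
  fit <- fit_fourier(prof, 2)
  expect_equal(glance(fit)$rmse, v3 / (2 * sqrt(2)), tolerance = 1e-9)
  # self-comparison of an exactly representable profile
  cmp <- profile_comparison(fit_fourier(prof, 3)$term, prof)
  expect_lt(cmp$max_abs, 1e-8)
})

test_that("round trip scan -> residual -> fit recovers ground truth over many draws", {
  mol <- make_toy_ligand("catechol_amine_like")
  withr::with_seed(31, {
    for (rep in 1:10) {
      truth <- fourier_torsion(runif(4, -5, 5))
      scan <- make_scan(mol, mol$dihedrals$beta, truth, seed = rep)
      fit <- fit_fourier(residual_profile(scan, mol), 4)
      expect_equal(fit$term$coefficients, truth$coefficients, tolerance = 1e-8)
    }
  })
})

test_that("noisy scans recover coefficients within propagated error", {
  mol <- make_toy_ligand("catechol_amine_like")
  truth <- fourier_torsion(c(2, -1, 3, 0.5))
  scan <- make_scan(mol, mol$dihedrals$gamma, truth, noise_sd = 0.5, seed = 77)
  fit <- fit_fourier(residual_profile(scan, mol), 4)
  td <- tidy(fit)
  dev <- abs(td$estimate[td$order > 0] - truth$coefficients)
  expect_true(all(dev <= 3 * td$std.error[td$order > 0] + 1e-9))
})

test_that("gromacs-style parameter line is formatted deterministically", {
  term <- fourier_torsion(c(1.234567891, 0, -2, 0.5), label = "gamma")
  line <- format_gromacs_dihedral(term, atoms = c("C1", "C2", "C3", "C4"))
  expect_match(line, "^C1 C2 C3 C4  5  1\\.234568  0\\.000000  -2\\.000000  0\\.500000 ; gamma$")
})
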