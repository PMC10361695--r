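# One-term Ogden (exponent 2) material: decomposition, energy, stress,
# tangent, and the tissue parameter table.

random_F <- function(n = 1, spread = 0.15) {
  # random admissible deformation gradients with J in about [0.8, 1.2]
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, 0, spread / 2), 3)
      J <- det(F)
      if (J > 0.8 && J < 1.2) return(F)
    }
  })
}

test_that("volumetric/isochoric decomposition satisfies its invariants", {
  st <- decompose_deformation(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$C_bar, diag(3))
  expect_equal(st$I1_bar, 3)
  expect_equal(st$lambda_bar, c(1, 1, 1))

  st <- decompose_deformation(diag(c(1.2, 1.0, 1 / 1.2)))
  expect_equal(st$J, 1)
  expect_equal(st$lambda_bar, c(1.2, 1.0, 1 / 1.2), tolerance = 1e-12)

  # pure dilatation has no isochoric part
  st <- decompose_deformation(2 * diag(3))
  expect_equal(st$J, 8)
  expect_equal(st$C_bar, diag(3))

  set.seed(42)
  for (F in random_F(25)) {
    st <- decompose_deformation(F)
    expect_lt(abs(det(st$C_bar) - 1), 1e-10)
    expect_equal(st$I1_bar, sum(st$lambda_bar^2), tolerance = 1e-12)
    i2 <- st$lambda_bar[1]^2 * st$lambda_bar[2]^2 +
      st$lambda_bar[2]^2 * st$lambda_bar[3]^2 +
      st$lambda_bar[3]^2 * st$lambda_bar[1]^2
    expect_equal(st$I2_bar, i2, tolerance = 1e-10)
  }
  expect_error(decompose_deformation(diag(c(1, 1, -1))), "positive")
})

test_that("strain energy matches hand-evaluated values", {
  p_wm <- ogden_params(0.68, 6.6)
  expect_equal(strain_energy(decompose_deformation(diag(3)), p_wm), 0)
  # isochoric diagonal stretch: volumetric term vanishes
  st <- decompose_deformation(diag(c(1.2, 1, 1 / 1.2)))
  expect_equal(strain_energy(st, p_wm), 0.34 * (1.44 + 1 + 1 / 1.44 - 3),
               tolerance = 1e-12)
  # pure dilatation: isochoric term vanishes, any mu
  J <- 1.1
  st <- decompose_deformation(J^(1 / 3) * diag(3))
  for (mu in c(0.1, 5)) {
    p <- ogden_params(mu, 3.3)
    expect_equal(strain_energy(st, p), 3.3 / 4 * (J^2 - 1 - 2 * log(J)),
                 tolerance = 1e-12)
  }
})

test_that("stress is the exact gradient of the energy (finite differences)", {
  set.seed(7)
  p <- ogden_params(0.34, 3.3)
  h <- 1e-6
  for (F in random_F(100)) {
    P <- pk1_stress(decompose_deformation(F), p)
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (strain_energy(decompose_deformation(Fp), p) -
                    strain_energy(decompose_deformation(Fm), p)) / (2 * h)
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-6)
  }
})

test_that("stress-free reference, volumetric pressure, and Cauchy symmetry", {
  p <- ogden_params(0.68, 6.6)
  expect_equal(pk1_stress(decompose_deformation(diag(3)), p), matrix(0, 3, 3))
  set.seed(11)
  for (F in random_F(20)) {
    st <- decompose_deformation(F)
    sig <- cauchy_stress(st, p)
    expect_equal(sig, t(sig), tolerance = 1e-10)
  }
  # pure dilatation: Cauchy stress is the volumetric pressure kappa/2 (J - 1/J)
  for (J in c(0.9, 1.05, 1.2)) {
    st <- decompose_deformation(J^(1 / 3) * diag(3))
    sig <- cauchy_stress(st, p)
    expect_equal(sig, (p$kappa / 2) * (J - 1 / J) * diag(3), tolerance = 1e-10)
  }
})

test_that("energy is frame-indifferent under random rotations", {
  set.seed(3)
  p <- ogden_params(0.68, 6.6)
  for (F in random_F(25)) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    e1 <- strain_energy(decompose_deformation(F), p)
    e2 <- strain_energy(decompose_deformation(Q %*% F), p)
    expect_lt(abs(e1 - e2), 1e-10)
  }
})

test_that("material tangent matches finite differences of the stress", {
  set.seed(5)
  p <- ogden_params(0.68, 6.6)
  h <- 1e-6
  for (F in random_F(20)) {
    st <- decompose_deformation(F)
    A <- material_tangent(st, p)
    Afd <- array(0, c(3, 3, 3, 3))
    for (k in 1:3) for (l in 1:3) {
      Fp <- F; Fp[k, l] <- Fp[k, l] + h
      Fm <- F; Fm[k, l] <- Fm[k, l] - h
      Afd[, , k, l] <- (pk1_stress(decompose_deformation(Fp), p) -
                        pk1_stress(decompose_deformation(Fm), p)) / (2 * h)
    }
    expect_lt(max(abs(A - Afd)) / max(abs(A)), 1e-5)
    # major symmetry of the associated elasticity tensor
    expect_equal(A, aperm(A, c(3, 4, 1, 2)), tolerance = 1e-9)
  }
})

test_that("tangent at identity is the isotropic small-strain tensor and is linear in the moduli", {
  mu <- 0.34; kappa <- 3.3
  A <- material_tangent(decompose_deformation(diag(3)), ogden_params(mu, kappa))
  lam <- kappa - 2 * mu / 3
  Aref <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    Aref[i, j, k, l] <- lam * (i == j) * (k == l) +
      mu * ((i == k) * (j == l) + (i == l) * (j == k))
  expect_equal(A, Aref, tolerance = 1e-12)

  set.seed(9)
  F <- random_F(1)[[1]]
  st <- decompose_deformation(F)
  A1 <- material_tangent(st, ogden_params(1, 0.001))
  A2 <- material_tangent(st, ogden_params(0.001, 1))
  for (s in list(c(0.5, 2), c(3, 0.7))) {
    Amix <- material_tangent(st, ogden_params(s[1] + 0.001 * s[2], s[2] + 0.001 * s[1]))
    expect_equal(Amix, s[1] * A1 + s[2] * A2, tolerance = 1e-8)
  }
})

test_that("incompressible uniaxial limit approaches mu (lambda - lambda^-2)", {
  # nominal axial stress of the incompressible exponent-2 Ogden response;
  # at finite kappa the lateral-stretch equilibrium is solved semi-
  # analytically and the nominal stress extrapolated over growing kappa
  mu <- 0.68; lam_target <- 1.1
  nominal_axial <- function(kappa) {
    sax <- stats::uniroot(function(s) uniaxial_state(s, mu, kappa)$lambda_ax - lam_target,
                          c(0, 1), tol = 1e-12)$root
    st <- uniaxial_state(sax, mu, kappa)
    # nominal stress = Cauchy * lateral area change
    sax * st$lambda_lat^2
  }
  p_inf <- mu * (lam_target - lam_target^-2)
  expect_equal(p_inf, 0.18602, tolerance = 1e-4)
  errs <- abs(vapply(c(1e2, 1e3, 1e4), nominal_axial, numeric(1)) - p_inf)
  expect_lt(errs[3] / p_inf, 1e-3)
  expect_true(all(diff(errs) < 0))
})

test_that("tissue table carries the published parameters and conversions", {
  tab <- default_tissue_table()
  expect_equal(tab$GM$mu, 0.34); expect_equal(tab$GM$kappa, 3.3)
  expect_equal(tab$WM$mu, 0.68); expect_equal(tab$WM$kappa, 6.6)
  expect_equal(tab$WMH$mu, tab$WM$mu)
  # SAS: E = 1 Pa, nu = 0.3 -> mu = 0.3846 Pa, kappa = 0.8333 Pa (stored kPa)
  expect_equal(tab$SAS$mu * 1000, 1 / 2.6, tolerance = 1e-12)
  expect_equal(tab$SAS$kappa * 1000, 1 / 1.2, tolerance = 1e-12)
  # gray matter Poisson ratio ~ 0.45 as published
  nu <- (3 * tab$GM$kappa - 2 * tab$GM$mu) / (6 * tab$GM$kappa + 2 * tab$GM$mu)
  expect_equal(nu, 0.45, tolerance = 2e-3)
  expect_equal(nu, 0.450195, tolerance = 1e-5)
  # sweep lower bound of the stiffness ratio
  expect_equal(default_tissue_table(1 / 4)$WM$mu, 0.085)
})
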