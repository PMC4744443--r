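mp_int <- muscle_params(fl_curve = "intercostal", a = 2.5, A = 0.8)
mp_dia <- muscle_params(fl_curve = "diaphragm", a = 2.5, A = 0.8)

test_that("reduced fibre stretch isolates the isochoric part", {
  expect_equal(fiber_stretch(diag(3), c(1, 0, 0)), 1.0)
  C <- diag(c(1.44, 1 / 1.2, 1 / 1.2))   # det C = 1, uniaxial isochoric
  expect_equal(fiber_stretch(C, c(1, 0, 0)), 1.2)
  # pure dilation leaves the reduced stretch at 1 for any direction
  set.seed(1)
  for (i in 1:5)
    expect_equal(fiber_stretch(4 * diag(3), random_unit_vector()), 1.0)
  expect_error(fiber_stretch(diag(c(1, 1, -1)), c(1, 0, 0)), "definite")
  expect_error(fiber_stretch(diag(3), c(1, 1, 0)), "unit")
})

test_that("reference configuration is stress-free for passive muscle", {
  kin <- kinematic_state(diag(3), c(0, 0, 1))
  S <- pk2_stress_muscle(kin, 0, mp_int)
  expect_equal(S, matrix(0, 3, 3), tolerance = 1e-14)
  expect_equal(strain_energy(kin, mp_int), mp_int$c)
  # energy gradient vanishes at the reference state; the parallel element has
  # a C1 kink at unit stretch, so probe the smooth matrix-only energy tightly
  # and the full law at a kink-appropriate O(h) tolerance
  mp_matrix <- muscle_params(A = 0, a = 2.5, fl_curve = "intercostal")
  g0 <- fd_stress_from_energy(diag(3), function(C)
    strain_energy(kinematic_from_C(C, c(0, 0, 1)), mp_matrix))
  expect_lt(max(abs(g0)), 1e-9)
  g <- fd_stress_from_energy(diag(3), function(C)
    strain_energy(kinematic_from_C(C, c(0, 0, 1)), mp_int))
  expect_lt(max(abs(g)), 1e-6)
})

test_that("active stress at unit stretch is the deviatoric fibre dyad", {
  N <- c(1, 0, 0)
  kin <- kinematic_state(diag(3), N)
  act <- activation_point(gamma = 1, alpha = 1)
  S <- pk2_stress_muscle(kin, 0, mp_int, act)
  expect_equal(S, mp_int$T0M * (tcrossprod(N) - diag(3) / 3),
               tolerance = 1e-12)
  # inactive muscle stores no contractile energy away from reference either
  kin2 <- kinematic_from_C(diag(c(1.21, 1 / 1.1, 1 / 1.1)), N)
  e_passive <- strain_energy(kin2, mp_int, activation_point(gamma = 0))
  e_active <- strain_energy(kin2, mp_int, act)
  expect_equal(e_active - e_passive,
               mp_int$T0M * fl_integral(mp_int$fl, kin2$lam_f_bar))
})

test_that("analytic stress is the exact gradient of the strain energy", {
  set.seed(42)
  N <- c(1, 0, 0)
  for (i in 1:20) {
    Nv <- if (i %% 2) N else random_unit_vector()
    C <- random_admissible_C(Nv)
    act <- activation_point(gamma = runif(1), alpha = runif(1))
    mp <- if (i %% 3) mp_int else mp_dia
    p <- runif(1, -0.1, 0.1)
    kin <- kinematic_from_C(C, Nv)
    S <- pk2_stress_muscle(kin, p, mp, act)
    S_fd <- fd_stress_from_energy(C, function(Cp)
      strain_energy(kinematic_from_C(Cp, Nv), mp, act))
    # S + p C^-1 must equal dU/dE
    diff <- S + p * solve(C) - S_fd
    expect_lt(max(abs(diff)) / max(max(abs(S_fd)), 1e-8), 1e-6)
  }
})

test_that("muscle law is transversely isotropic about the fibre axis", {
  set.seed(11)
  N <- random_unit_vector()
  C <- random_admissible_C(N)
  act <- activation_point(gamma = 0.7, alpha = 0.9)
  S <- pk2_stress_muscle(kinematic_from_C(C, N), 0.03, mp_dia, act)
  for (ang in c(15, 97, 211)) {
    Q <- rotation_matrix(N, ang)
    Cr <- t(Q) %*% C %*% Q
    Sr <- pk2_stress_muscle(kinematic_from_C(Cr, N), 0.03, mp_dia, act)
    expect_lt(max(abs(Sr - t(Q) %*% S %*% Q)), 1e-10)
  }
})

test_that("Saint Venant-Kirchhoff stress matches its closed forms", {
  expect_equal(pk2_stress_isotropic(kinematic_state(diag(3)),
                                    isotropic_params(5, 10)),
               matrix(0, 3, 3))
  bone <- isotropic_params(mu = 569.23, lam = 853.85)
  eps <- 1e-6
  kin <- kinematic_state(diag(c(1 + eps, 1, 1)))
  S <- pk2_stress_isotropic(kin, bone)
  expect_equal(S[1, 1], (853.85 + 2 * 569.23) * eps, tolerance = 1e-5)
  # pure shear, cartilage: S12 = 2 mu E12
  cart <- isotropic_params(mu = 65.38, lam = 98.08)
  E <- matrix(0, 3, 3); E[1, 2] <- E[2, 1] <- 0.01
  kin2 <- kinematic_from_C(diag(3) + 2 * E)
  expect_equal(pk2_stress_isotropic(kin2, cart)[1, 2], 1.3076,
               tolerance = 1e-12)
})

test_that("analytic tangent matches finite differences and is symmetric", {
  set.seed(99)
  # SVK: closed-form constant tangent
  bone <- isotropic_params(mu = 569.23, lam = 853.85)
  kin <- kinematic_state(diag(3))
  D_svk <- material_tangent(kin, 0, bone)
  D_ref <- matrix(0, 6, 6)
  D_ref[1:3, 1:3] <- 853.85
  diag(D_ref) <- diag(D_ref) + c(rep(2 * 569.23, 3), rep(0, 3))
  diag(D_ref)[4:6] <- 569.23
  expect_equal(D_svk, D_ref)
  # muscle: FD oracle agreement and major symmetry on random states
  for (i in 1:8) {
    N <- random_unit_vector()
    C <- random_admissible_C(N)
    act <- activation_point(gamma = runif(1), alpha = 1)
    p <- runif(1, -0.05, 0.05)
    kin <- kinematic_from_C(C, N)
    D <- material_tangent(kin, p, mp_int, act)
    expect_lt(max(abs(D - t(D))), 1e-10 * max(abs(D)))
    D_fd <- fd_tangent_from_stress(C, function(Cp)
      pk2_stress_muscle(kinematic_from_C(Cp, N), p, mp_int, act))
    expect_lt(max(abs(D - D_fd)) / max(abs(D_fd)), 1e-5)
    # the package's own FD mode agrees with the analytic path as well
    D_own <- material_tangent(kin, p, mp_int, act, method = "fd")
    expect_lt(max(abs(D - D_own)) / max(abs(D)), 1e-5)
  }
})
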