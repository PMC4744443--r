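# Independent oracles and fixture builders shared across the test suite.
# Everything here is deliberately written against the public API only, using
# its own finite-difference machinery, so it can serve as an independent
# check on the analytic stress and tangent implementations.

voigt_pairs <- cbind(i = c(1L, 2L, 3L, 1L, 1L, 2L),
                     j = c(1L, 2L, 3L, 2L, 3L, 3L))

sym_from_voigt <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# gradient of a scalar function of C w.r.t. Green-Lagrange strain, central
# differences with symmetric C perturbations; returns a symmetric 3x3 "S"
fd_stress_from_energy <- function(C, energy_fun, h = 1e-6) {
  g <- numeric(6)
  for (q in 1:6) {
    k <- voigt_pairs[q, 1]; l <- voigt_pairs[q, 2]
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[k, l] + h
    dC[l, k] <- dC[l, k] + h
    g[q] <- (energy_fun(C + dC) - energy_fun(C - dC)) / (2 * h)
  }
  sym_from_voigt(g)
}

# 6x6 Voigt tangent dS/dE from central differences of a stress function of C
fd_tangent_from_stress <- function(C, stress_fun, h = 1e-6) {
  D <- matrix(0, 6, 6)
  for (q in 1:6) {
    k <- voigt_pairs[q, 1]; l <- voigt_pairs[q, 2]
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[k, l] + h
    dC[l, k] <- dC[l, k] + h
    dS <- (stress_fun(C + dC) - stress_fun(C - dC)) / (2 * h)
    D[, q] <- c(dS[1, 1], dS[2, 2], dS[3, 3], dS[1, 2], dS[1, 3], dS[2, 3])
  }
  D
}

# random SPD right Cauchy-Green tensor with prescribed determinant range,
# keeping the reduced fibre stretch away from force-length breakpoints so
# finite differences of the (piecewise) energy are valid
random_admissible_C <- function(N = c(1, 0, 0), det_range = c(0.8, 1.25),
                                spread = 0.15, kink_tol = 2e-4) {
  repeat {
    Fm <- diag(3) + matrix(runif(9, -spread, spread), 3, 3)
    if (det(Fm) <= 0.1) next
    C <- crossprod(Fm)
    target <- runif(1, det_range[1], det_range[2])
    C <- C * (target / det(C))^(1 / 3)
    lb <- fiber_stretch(C, N)
    if (min(abs(lb - seq(0.6, 1.2, by = 0.1))) > kink_tol) return(C)
  }
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# closed-form nominal axial stress for incompressible uniaxial stretch along
# the fibre with traction-free lateral faces: hydrostatic pressure eliminated
# from S22 = 0, derived independently of the FEM path
uniaxial_nominal_stress <- function(lam, mp, gamma = 0, alpha = 1) {
  I1b <- lam^2 + 2 / lam
  u1 <- mp$b * mp$c * exp(mp$b * (I1b - 3))
  Tf <- mp$T0M * (f_pe(lam, mp$a, mp$A) +
                    fl_eval(mp$fl, lam) * gamma * alpha)
  # S22 = -p/ (1/lam)^-1 ... with C = diag(lam^2, 1/lam, 1/lam), J = 1:
  # S22 = -p*lam + 2 u1 (1 - I1b*lam/3) - Tf*lam^2/3 = 0
  p <- (2 * u1 * (1 - I1b * lam / 3) - Tf * lam^2 / 3) / lam
  S11 <- -p / lam^2 + 2 * u1 * (1 - I1b / (3 * lam^2)) + Tf * 2 / (3 * lam)
  lam * S11                      # first Piola-Kirchhoff / nominal stress
}
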