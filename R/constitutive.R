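#' Kinematic state at a material point
#'
#' Collects the deformation measures the constitutive laws consume: the
#' deformation gradient `F`, right Cauchy-Green tensor `C = t(F) %*% F`, its
#' determinant-related quantities, the first reduced (isochoric) invariant
#' `I1bar = J^(-2/3) tr(C)` and the reduced fibre stretch along the reference
#' fibre direction `N`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @param N Reference fibre direction, unit 3-vector (checked to 1e-12).
#'   May be `NULL` for isotropic materials.
#' @return An object of class `kinematic_state` with fields `F`, `C`, `J`,
#'   `I1bar`, `lam_f_bar`, `N`.
#' @export
kinematic_state <- function(F, N = NULL) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("kinematic_state: det(F) must be > 0")
  C <- crossprod(F)
  st <- list(F = F, C = C, J = J,
             I1bar = J^(-2 / 3) * sum(diag(C)),
             lam_f_bar = NA_real_, N = NULL)
  if (!is.null(N)) {
    N <- .check_unit(N)
    st$N <- N
    st$lam_f_bar <- sqrt(J^(-2 / 3) * drop(crossprod(N, C %*% N)))
  }
  class(st) <- "kinematic_state"
  st
}

#' Kinematic state from a right Cauchy-Green tensor
#'
#' As [kinematic_state()] but starting from `C` (symmetric positive
#' definite); the stored `F` is the SPD square root of `C`, which is
#' immaterial to the constitutive response (all laws depend on `C` only).
#'
#' @param C 3x3 symmetric positive definite tensor.
#' @param N Reference fibre direction (unit 3-vector) or `NULL`.
#' @return A `kinematic_state`.
#' @export
kinematic_from_C <- function(C, N = NULL) {
  C <- .check_spd(C)
  e <- eigen(C, symmetric = TRUE)
  Fs <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  kinematic_state(Fs, N)
}

.check_unit <- function(N, tol = 1e-12) {
  N <- as.numeric(N)
  stopifnot(length(N) == 3L)
  if (abs(sum(N^2) - 1) > 10 * tol)
    stop("fibre direction N must be a unit vector")
  N
}

.check_spd <- function(C) {
  C <- as.matrix(C)
  stopifnot(identical(dim(C), c(3L, 3L)))
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
    stop("C must be symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("C must be positive definite")
  (C + t(C)) / 2
}

#' Reduced fibre stretch
#'
#' `lam_f_bar = sqrt(J^(-2/3) * (N . C N))` with `J = sqrt(det(C))`: the
#' stretch ratio along the fibre with the volumetric part factored out, so a
#' pure dilation leaves it at 1.
#'
#' @param C 3x3 symmetric positive definite right Cauchy-Green tensor.
#' @param N Unit reference fibre direction.
#' @return The reduced fibre stretch (strictly positive scalar).
#' @export
fiber_stretch <- function(C, N) {
  C <- .check_spd(C)
  N <- .check_unit(N)
  J <- sqrt(det(C))
  sqrt(J^(-2 / 3) * drop(crossprod(N, C %*% N)))
}

# ---- Voigt machinery (order 11, 22, 33, 12, 13, 23) -------------------------

.VOIGT_I <- c(1L, 2L, 3L, 1L, 1L, 2L)
.VOIGT_J <- c(1L, 2L, 3L, 2L, 3L, 3L)

# symmetric 3x3 -> Voigt 6-vector of representative components
.sv <- function(T) c(T[1, 1], T[2, 2], T[3, 3], T[1, 2], T[1, 3], T[2, 3])

# Voigt 6-vector -> symmetric 3x3
.vs <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# d(Cinv)/dC as a 6x6 of representative components:
# -(Ci_ik Ci_jl + Ci_il Ci_jk)/2 at (ij),(kl) representatives
.dinv_voigt <- function(Ci) {
  D <- matrix(0, 6, 6)
  for (p in 1:6) {
    i <- .VOIGT_I[p]; j <- .VOIGT_J[p]
    for (q in 1:6) {
      k <- .VOIGT_I[q]; l <- .VOIGT_J[q]
      D[p, q] <- -0.5 * (Ci[i, k] * Ci[j, l] + Ci[i, l] * Ci[j, k])
    }
  }
  D
}

# ---- internal material-point kernels ---------------------------------------
# These operate on raw C (plus precomputed inverse/determinant) for speed in
# the element loops; the exported functions wrap them.

# muscle deviatoric (isochoric) PK2 stress: matrix + fibre terms, no pressure
.muscle_S_dev <- function(C, Ci, detC, N, mp, ga) {
  J23 <- detC^(-1 / 3)            # J^(-2/3) with J = sqrt(det C)
  trC <- C[1, 1] + C[2, 2] + C[3, 3]
  I1b <- J23 * trC
  u1 <- mp$b * mp$c * exp(mp$b * (I1b - 3))
  H <- J23 * diag(3) - (I1b / 3) * Ci
  S <- 2 * u1 * H
  lb <- NA_real_
  if (!is.null(N)) {
    lb <- sqrt(J23 * drop(crossprod(N, C %*% N)))
    Tf <- mp$T0M * (f_pe(lb, mp$a, mp$A) + fl_eval(mp$fl, lb) * ga)
    if (Tf != 0) {
      M <- tcrossprod(N)
      S <- S + Tf * ((J23 / lb) * M - (lb / 3) * Ci)
    }
  }
  list(S = S, I1b = I1b, lb = lb, u1 = u1, J23 = J23)
}

# tangent dS_dev/dE (6x6 Voigt, engineering shear) for the muscle law
.muscle_D_dev <- function(C, Ci, detC, N, mp, ga) {
  J23 <- detC^(-1 / 3)
  trC <- C[1, 1] + C[2, 2] + C[3, 3]
  I1b <- J23 * trC
  u1 <- mp$b * mp$c * exp(mp$b * (I1b - 3))
  Civ <- .sv(Ci)
  Iv <- c(1, 1, 1, 0, 0, 0)
  Hv <- J23 * Iv - (I1b / 3) * Civ
  Dci <- .dinv_voigt(Ci)
  # matrix part: 2 u1' H x H + 2 u1 dH/dC
  Dc <- 2 * mp$b * u1 * outer(Hv, Hv) +
    2 * u1 * (-(J23 / 3) * (outer(Iv, Civ) + outer(Civ, Iv)) +
                (I1b / 9) * outer(Civ, Civ) - (I1b / 3) * Dci)
  if (!is.null(N)) {
    lb <- sqrt(J23 * drop(crossprod(N, C %*% N)))
    Tf <- mp$T0M * (f_pe(lb, mp$a, mp$A) + fl_eval(mp$fl, lb) * ga)
    Tp <- mp$T0M * (.f_pe_deriv(lb, mp$a, mp$A) + fl_deriv(mp$fl, lb) * ga)
    if (Tf != 0 || Tp != 0) {
      Mv <- .sv(tcrossprod(N))
      Wv <- (J23 / lb) * Mv - (lb / 3) * Civ
      Dc <- Dc + (Tp / 2) * outer(Wv, Wv) +
        Tf * (-(J23^2 / (2 * lb^3)) * outer(Mv, Mv) -
                (J23 / (6 * lb)) * (outer(Mv, Civ) + outer(Civ, Mv)) +
                (lb / 18) * outer(Civ, Civ) - (lb / 3) * Dci)
    }
  }
  2 * Dc                                   # d/dE = 2 d/dC
}

# volumetric constraint stress dU_V/dE = 2 det(C) Cinv, scaled by xi
.vol_S <- function(Ci, detC, xi) (2 * xi * detC) * Ci

.vol_D <- function(Ci, detC, xi) {
  Civ <- .sv(Ci)
  (4 * xi * detC) * (outer(Civ, Civ) + .dinv_voigt(Ci))
}

# Saint Venant-Kirchhoff stress and (constant) tangent
.svk_S <- function(C, ip) {
  E <- (C - diag(3)) / 2
  ip$lam * sum(diag(E)) * diag(3) + 2 * ip$mu * E
}

.svk_D <- function(ip) {
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- ip$lam
  diag(D)[1:3] <- diag(D)[1:3] + 2 * ip$mu
  diag(D)[4:6] <- ip$mu
  D
}

# ---- exported material-point API -------------------------------------------

#' Strain energy of the muscle law at a material point
#'
#' `U_R = U_I(I1bar) + U_PE(lam_f_bar) + U_CE(lam_f_bar, alpha, gamma)` in
#' MPa, with `U_I = c * exp(b * (I1bar - 3))`, `U_PE` the closed-form
#' integral of `T0M * f_PE` from 1 to the reduced fibre stretch, and `U_CE`
#' the exact branchwise integral of `T0M * f_CE * alpha * gamma`. At the
#' reference configuration `U_R = c` (the energy constant is immaterial to
#' the stress). `U_CE` is negative for shortened active fibre, reflecting the
#' work the contractile element can perform.
#'
#' @param kin A [kinematic_state] with a fibre direction.
#' @param params A [muscle_params] object.
#' @param act An [activation_point] (default: passive).
#' @return Scalar energy density (MPa).
#' @export
strain_energy <- function(kin, params, act = activation_point()) {
  stopifnot(inherits(kin, "kinematic_state"), inherits(params, "muscle_params"))
  U <- params$c * exp(params$b * (kin$I1bar - 3))
  if (!is.null(kin$N)) {
    lb <- kin$lam_f_bar
    U <- U + params$T0M * .f_pe_integral(lb, params$a, params$A) +
      params$T0M * act$gamma * act$alpha * fl_integral(params$fl, lb)
  }
  U
}

#' Second Piola-Kirchhoff stress of the active muscle law
#'
#' `S = -p C^-1 + 2 dU_I/dC + 2 dU_f/dC` with the isochoric derivatives taken
#' exactly (including the `J^(-2/3)` factors on the reduced invariants), so
#' the stress is the exact gradient of [strain_energy()] plus the hydrostatic
#' term. For a passive material at the reference configuration the stress
#' vanishes; with active fibre (`gamma > 0`) the stress at unit stretch is
#' the deviatoric rank-one fibre stress `T0M * (N x N - I/3)` scaled by the
#' activation, a feature of the active law rather than a defect.
#'
#' @param kin A [kinematic_state] with a fibre direction.
#' @param p_hydro Hydrostatic pressure `p` (MPa); related to the
#'   incompressibility multiplier by `p = -2 xi`.
#' @param params A [muscle_params] object.
#' @param act An [activation_point].
#' @return Symmetric 3x3 stress tensor (MPa).
#' @export
pk2_stress_muscle <- function(kin, p_hydro = 0, params,
                              act = activation_point()) {
  stopifnot(inherits(kin, "kinematic_state"), inherits(params, "muscle_params"))
  C <- kin$C
  Ci <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("pk2_stress_muscle: singular or non-SPD C"))
  res <- .muscle_S_dev(C, Ci, det(C), kin$N, params,
                       act$gamma * act$alpha)
  res$S - p_hydro * Ci
}

#' Second Piola-Kirchhoff stress of the Saint Venant-Kirchhoff law
#'
#' `S = lam * tr(E) I + 2 mu E` with `E = (C - I)/2`, used for the passive
#' thoracic tissues (bone, cartilage, tendon).
#'
#' @param kin A [kinematic_state].
#' @param params An [isotropic_params] object.
#' @return Symmetric 3x3 stress tensor (MPa).
#' @export
pk2_stress_isotropic <- function(kin, params) {
  stopifnot(inherits(kin, "kinematic_state"),
            inherits(params, "isotropic_params"))
  .svk_S(kin$C, params)
}

#' Consistent material tangent at a material point
#'
#' Returns `dS/dE` in Voigt form (6x6; strain ordered
#' `E11, E22, E33, 2E12, 2E13, 2E23`, stress `S11, S22, S33, S12, S13, S23`),
#' the linearisation used by the Newton solver. The analytic form carries the
#' major and minor symmetries of hyperelasticity (the pressure term included
#' here is the linearisation of `-p C^-1` at fixed `p`).
#'
#' @param kin A [kinematic_state].
#' @param p_hydro Hydrostatic pressure (MPa), muscle law only.
#' @param params A [muscle_params] or [isotropic_params] object.
#' @param act An [activation_point] (muscle law only).
#' @param method `"analytic"` (default) or `"fd"` (central differences of the
#'   stress, available as an independent check).
#' @return 6x6 tangent matrix (MPa).
#' @export
material_tangent <- function(kin, p_hydro = 0, params,
                             act = activation_point(),
                             method = c("analytic", "fd")) {
  method <- match.arg(method)
  stopifnot(inherits(kin, "kinematic_state"))
  if (method == "fd") return(.tangent_fd(kin, p_hydro, params, act))
  if (inherits(params, "isotropic_params")) return(.svk_D(params))
  C <- kin$C
  Ci <- chol2inv(chol(C))
  D <- .muscle_D_dev(C, Ci, det(C), kin$N, params, act$gamma * act$alpha)
  # -p dCi/dE = -2 p dCi/dC
  D - 2 * p_hydro * .dinv_voigt(Ci)
}

# central-difference tangent w.r.t. E, perturbing symmetric C pairs
.tangent_fd <- function(kin, p_hydro, params, act, h = 1e-6) {
  stress <- function(C) {
    k <- kinematic_from_C(C, kin$N)
    if (inherits(params, "muscle_params"))
      pk2_stress_muscle(k, p_hydro, params, act)
    else pk2_stress_isotropic(k, params)
  }
  D <- matrix(0, 6, 6)
  for (q in 1:6) {
    k <- .VOIGT_I[q]; l <- .VOIGT_J[q]
    dC <- matrix(0, 3, 3)
    # symmetric perturbation: dC_kl = dC_lk = h, which advances the Voigt
    # strain component (E_kk, or 2E_kl for shear) by exactly h in both cases
    dC[k, l] <- dC[k, l] + h
    dC[l, k] <- dC[l, k] + h
    Sp <- stress(kin$C + dC)
    Sm <- stress(kin$C - dC)
    D[, q] <- .sv((Sp - Sm) / (2 * h))
  }
  D
}
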