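#' Constitutive parameters for active skeletal muscle
#'
#' Parameter set of the incompressible, transversely isotropic hyperelastic
#' Hill-type muscle law. The isotropic matrix contributes an exponential
#' energy `c * exp(b * (I1bar - 3))`; the fibre contributes a passive
#' parallel-element stress `T0M * f_PE(lam)` and an active contractile-element
#' stress `T0M * f_CE(lam) * alpha * gamma`.
#'
#' Defaults: `T0M = 0.3` MPa and matrix constants `c = 0.009348` MPa,
#' `b = 1.4939` are the respiratory-muscle calibration used throughout the
#' package; the passive fibre constants `a`, `A` default to values
#' representative of skeletal muscle but should be treated as configuration
#' inputs whenever the passive response matters.
#'
#' @param T0M Maximum nominal muscle stress (MPa, >= 0).
#' @param a Passive exponent constant (dimensionless, > 0).
#' @param A Passive amplitude constant (dimensionless, >= 0).
#' @param c Matrix amplitude (MPa, > 0).
#' @param b Matrix exponent (dimensionless, > 0).
#' @param fl_curve Active force-length curve: `"intercostal"`, `"diaphragm"`,
#'   or an [fl_curve] object (e.g. from [fl_from_table()]).
#' @param fl_smooth Optional taper width smoothing the curve's upper cut-off
#'   (0 disables; see [fl_taper()]).
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(T0M = 0.3, a = 12.43, A = 0.28,
                          c = 0.009348, b = 1.4939,
                          fl_curve = "intercostal", fl_smooth = 0) {
  stopifnot(T0M >= 0, a > 0, A >= 0, c > 0, b > 0, fl_smooth >= 0)
  if (is.character(fl_curve)) {
    fl_curve <- switch(fl_curve,
                       intercostal = fl_intercostal(),
                       diaphragm = fl_diaphragm(),
                       stop("unknown fl_curve identifier: ", fl_curve))
  }
  stopifnot(inherits(fl_curve, "fl_curve"))
  if (fl_smooth > 0) fl_curve <- fl_taper(fl_curve, fl_smooth)
  structure(list(T0M = T0M, a = a, A = A, c = c, b = b, fl = fl_curve),
            class = c("muscle_params", "material_params"))
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(paste0("<muscle_params: T0M=%g MPa, a=%g, A=%g, ",
                     "c=%g MPa, b=%g, fl='%s'>\n"),
              x$T0M, x$a, x$A, x$c, x$b, x$fl$name))
  invisible(x)
}

#' Isotropic elastic parameters for passive tissues
#'
#' Saint Venant-Kirchhoff parameters for bone, cartilage and tendon. The law
#' is linear in the Green-Lagrange strain, so it reduces to classical linear
#' elasticity at small strain while remaining well defined under the finite
#' kinematics of the solver.
#'
#' @param mu Lame shear modulus (MPa, > 0).
#' @param lam Lame first parameter (MPa, >= 0).
#' @return An object of class `isotropic_params`.
#' @export
isotropic_params <- function(mu, lam) {
  stopifnot(mu > 0, lam >= 0)
  structure(list(mu = mu, lam = lam),
            class = c("isotropic_params", "material_params"))
}

#' @export
print.isotropic_params <- function(x, ...) {
  cat(sprintf("<isotropic_params: mu=%g MPa, lambda=%g MPa>\n", x$mu, x$lam))
  invisible(x)
}

#' Reference material set for thoracic tissues
#'
#' Named list of ready-made parameter objects: Saint Venant-Kirchhoff
#' constants for `bone` (mu = 569.23, lambda = 853.85 MPa), `cartilage`
#' (65.38, 98.08 MPa) and `tendon` (5.18, 10.05 MPa), plus muscle parameter
#' sets for the `intercostal` muscles and `diaphragm`
#' (T0M = 0.3 MPa, c = 0.009348 MPa, b = 1.4939, with the matching
#' force-length curve). `central_tendon` aliases `tendon`.
#'
#' @param ... Arguments forwarded to [muscle_params()] for the two muscle
#'   entries (e.g. to override `a` and `A`).
#' @return Named list of `material_params` objects.
#' @export
tissue_materials <- function(...) {
  tendon <- isotropic_params(mu = 5.18, lam = 10.05)
  list(bone = isotropic_params(mu = 569.23, lam = 853.85),
       cartilage = isotropic_params(mu = 65.38, lam = 98.08),
       tendon = tendon,
       central_tendon = tendon,
       intercostal = muscle_params(fl_curve = "intercostal", ...),
       diaphragm = muscle_params(fl_curve = "diaphragm", ...))
}

#' Activation state at a material point
#'
#' @param gamma Activation level in \[0, 1\] (spatial field value).
#' @param alpha Temporal activation in \[0, 1\] (waveform value).
#' @return An object of class `activation_point`.
#' @export
activation_point <- function(gamma = 0, alpha = 1) {
  stopifnot(gamma >= 0, gamma <= 1, alpha >= 0, alpha <= 1)
  structure(list(gamma = gamma, alpha = alpha), class = "activation_point")
}
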