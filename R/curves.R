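#' Force-length curves for the contractile and parallel elements
#'
#' Skeletal muscle in this package follows a Hill-type description: total
#' fibre stress is the sum of a passive parallel-element (PE) contribution and
#' an active contractile-element (CE) contribution, both expressed per unit
#' reference area and normalised by the maximum nominal muscle stress
#' `T0M`. The CE force-length relationship is a piecewise-linear curve of the
#' reduced fibre stretch, with distinct calibrations for the intercostal
#' muscles and the diaphragm; both peak at 1.0 for unit stretch and vanish
#' outside the stretch interval \[0.6, 1.2).
#'
#' @name fl-curves
#' @keywords internal
NULL

#' Construct a piecewise-linear force-length curve
#'
#' @param breaks Strictly increasing breakpoints of the stretch axis. The
#'   curve is `slope[k] * lambda + intercept[k]` on
#'   `[breaks[k], breaks[k+1])` and identically zero outside
#'   `[breaks[1], breaks[n])`.
#' @param slope,intercept Per-segment linear coefficients
#'   (`length(breaks) - 1` each).
#' @param name Curve label used in printing and configuration files.
#' @return An object of class `fl_curve`.
#' @seealso [fl_intercostal()], [fl_diaphragm()], [fl_from_table()]
#' @export
fl_curve <- function(breaks, slope, intercept, name = "custom") {
  breaks <- as.numeric(breaks)
  slope <- as.numeric(slope)
  intercept <- as.numeric(intercept)
  stopifnot(length(breaks) >= 2L, all(diff(breaks) > 0),
            length(slope) == length(breaks) - 1L,
            length(intercept) == length(slope))
  structure(list(breaks = breaks, slope = slope, intercept = intercept,
                 name = name),
            class = "fl_curve")
}

#' @export
print.fl_curve <- function(x, ...) {
  cat(sprintf("<fl_curve '%s': %d segments on [%g, %g)>\n",
              x$name, length(x$slope), x$breaks[1],
              x$breaks[length(x$breaks)]))
  invisible(x)
}

#' Active force-length curve of the intercostal muscles
#'
#' Six linear branches on \[0.6, 1.2) peaking at 1.0 for unit reduced fibre
#' stretch, zero elsewhere.
#'
#' @return An `fl_curve`.
#' @export
fl_intercostal <- function() {
  fl_curve(breaks = seq(0.6, 1.2, by = 0.1),
           slope = c(0.85, 2.43, 3.32, 3.10, -2.30, -3.20),
           intercept = c(-0.48, -1.59, -2.30, -2.10, 3.30, 4.29),
           name = "intercostal")
}

#' Active force-length curve of the diaphragm
#'
#' Six linear branches on \[0.6, 1.2) peaking at 1.0 for unit reduced fibre
#' stretch, zero elsewhere.
#'
#' @return An `fl_curve`.
#' @export
fl_diaphragm <- function() {
  fl_curve(breaks = seq(0.6, 1.2, by = 0.1),
           slope = c(1.80, 2.37, 1.61, 1.42, -0.55, -2.11),
           intercept = c(-0.80, -1.20, -0.59, -0.42, 1.55, 3.27),
           name = "diaphragm")
}

#' Build a force-length curve from a breakpoint/value table
#'
#' Linear interpolation between tabulated points; zero outside the tabulated
#' stretch range (a discontinuous drop at the ends is permitted, as in the
#' shipped curves).
#'
#' @param lambda Strictly increasing stretch values.
#' @param value Curve values at `lambda`.
#' @param name Curve label.
#' @return An `fl_curve`.
#' @export
fl_from_table <- function(lambda, value, name = "table") {
  stopifnot(length(lambda) == length(value), length(lambda) >= 2L,
            all(diff(lambda) > 0))
  m <- diff(value) / diff(lambda)
  q <- value[-length(value)] - m * lambda[-length(lambda)]
  fl_curve(lambda, m, q, name = name)
}

#' Taper the upper cut-off of a force-length curve
#'
#' The printed CE curves drop discontinuously to zero at the upper end of
#' their support. That jump is faithful to the calibration but can slow the
#' Newton solver when fibre stretches cross it; this helper appends a linear
#' taper of the given width so the curve reaches zero continuously. Using it
#' is always an explicit, logged choice (`message()`), never a default.
#'
#' @param curve An `fl_curve`.
#' @param width Stretch width of the taper segment (> 0).
#' @return A new `fl_curve` with the taper appended.
#' @export
fl_taper <- function(curve, width) {
  stopifnot(inherits(curve, "fl_curve"), width > 0)
  nb <- length(curve$breaks)
  top <- curve$breaks[nb]
  v_end <- curve$slope[nb - 1L] * top + curve$intercept[nb - 1L]
  if (abs(v_end) < 1e-12) return(curve)
  m <- -v_end / width
  q <- v_end - m * top
  message(sprintf("fl_taper: smoothing %s cut-off at %.3g over width %.3g",
                  curve$name, top, width))
  fl_curve(c(curve$breaks, top + width), c(curve$slope, m),
           c(curve$intercept, q), name = paste0(curve$name, "+taper"))
}

#' Evaluate a force-length curve
#'
#' @param curve An `fl_curve`.
#' @param lam Vector of reduced fibre stretches.
#' @return Curve values (zero outside the support).
#' @export
fl_eval <- function(curve, lam) {
  k <- findInterval(lam, curve$breaks)
  out <- numeric(length(lam))
  inside <- k >= 1L & k <= length(curve$slope)
  ki <- k[inside]
  out[inside] <- curve$slope[ki] * lam[inside] + curve$intercept[ki]
  out
}

#' Derivative of a force-length curve
#'
#' Piecewise-constant slope; at breakpoints the right-hand branch applies,
#' consistent with the half-open branch intervals.
#'
#' @inheritParams fl_eval
#' @return Slopes (zero outside the support).
#' @export
fl_deriv <- function(curve, lam) {
  k <- findInterval(lam, curve$breaks)
  out <- numeric(length(lam))
  inside <- k >= 1L & k <= length(curve$slope)
  out[inside] <- curve$slope[k[inside]]
  out
}

#' Integral of a force-length curve from unit stretch
#'
#' Computes the exact integral of the piecewise-linear curve from 1 to `lam`
#' (negative when `lam < 1`), which is the normalised strain energy stored by
#' the corresponding Hill element.
#'
#' @inheritParams fl_eval
#' @return The signed integrals.
#' @export
fl_integral <- function(curve, lam) {
  .fl_prim(curve, lam) - .fl_prim(curve, 1)
}

# primitive P(x) = int_{breaks[1]}^{clamp(x)} f dt, constant outside support
.fl_prim <- function(curve, x) {
  b <- curve$breaks
  n <- length(b)
  # cumulative integral at the breakpoints
  seg <- 0.5 * curve$slope * (b[-1]^2 - b[-n]^2) +
    curve$intercept * (b[-1] - b[-n])
  cum <- c(0, cumsum(seg))
  xc <- pmin(pmax(x, b[1]), b[n])
  k <- findInterval(xc, b, rightmost.closed = TRUE)
  cum[k] + 0.5 * curve$slope[pmin(k, n - 1L)] * (xc^2 - b[k]^2) +
    curve$intercept[pmin(k, n - 1L)] * (xc - b[k])
}

#' Passive force-length relationship of the parallel element
#'
#' `f_PE(lam) = 2 a A (lam - 1) exp(a (lam - 1)^2)` for `lam > 1` and zero
#' otherwise; continuous at unit stretch and monotone increasing beyond it.
#'
#' @param lam_f_bar Reduced fibre stretch (> 0), vectorised.
#' @param a Passive exponent constant (dimensionless, > 0).
#' @param A Passive amplitude constant (dimensionless, >= 0).
#' @return Normalised passive stress values (non-negative).
#' @export
f_pe <- function(lam_f_bar, a, A) {
  stopifnot(all(lam_f_bar > 0), a > 0, A >= 0)
  d <- lam_f_bar - 1
  ifelse(d > 0, 2 * a * A * d * exp(a * d^2), 0)
}

# derivative of f_pe w.r.t. stretch (right-continuous at 1)
.f_pe_deriv <- function(lam, a, A) {
  d <- lam - 1
  ifelse(d > 0, 2 * a * A * exp(a * d^2) * (1 + 2 * a * d^2), 0)
}

# closed-form integral of f_pe from 1 to lam: A (exp(a (lam-1)^2) - 1)
.f_pe_integral <- function(lam, a, A) {
  d <- pmax(lam - 1, 0)
  A * (exp(a * d^2) - 1)
}

#' Active force-length value of the intercostal muscles
#'
#' @param lam_f_bar Reduced fibre stretch (> 0), vectorised.
#' @return Normalised active stress capacity (1.0 at unit stretch).
#' @export
f_ce_intercostal <- function(lam_f_bar) {
  stopifnot(all(lam_f_bar > 0))
  fl_eval(fl_intercostal(), lam_f_bar)
}

#' Active force-length value of the diaphragm
#'
#' @param lam_f_bar Reduced fibre stretch (> 0), vectorised.
#' @return Normalised active stress capacity (1.0 at unit stretch).
#' @export
f_ce_diaphragm <- function(lam_f_bar) {
  stopifnot(all(lam_f_bar > 0))
  fl_eval(fl_diaphragm(), lam_f_bar)
}
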