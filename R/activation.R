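# Spatial activation fields gamma(x) for the respiratory muscle groups and
# temporal activation waveforms alpha(t). The spatial distributions follow
# the electromyographic pattern of the inspiratory and expiratory
# intercostals: separable piecewise-linear ramps in normalised anatomical
# coordinates whose extremes reproduce the documented maxima (gamma = 1 at
# the sternal end of the parasternals, at the dorsal top interspace for the
# external intercostals, at the dorsal bottom interspace for the internal
# intercostals).

#' Temporal activation waveform
#'
#' Piecewise-linear breakpoint table `alpha(t)`; values are clamped to the
#' first/last breakpoint outside the table span.
#'
#' @param t Strictly increasing times (s).
#' @param alpha Activation values in \[0, 1\].
#' @return An object of class `waveform`.
#' @export
waveform <- function(t, alpha) {
  stopifnot(length(t) == length(alpha), length(t) >= 2L, all(diff(t) > 0),
            all(alpha >= 0), all(alpha <= 1))
  structure(list(t = as.numeric(t), alpha = as.numeric(alpha)),
            class = "waveform")
}

#' Default quiet-breathing activation waveform
#'
#' Smooth rise-plateau-fall over one breath: inspiratory rise to full
#' activation at 40 % of the cycle, a short plateau, and relaxation
#' completing at 90 %.
#'
#' @param duration Breath duration (s, default 5).
#' @return A [waveform].
#' @export
default_breath_waveform <- function(duration = 5) {
  stopifnot(duration > 0)
  waveform(duration * c(0, 0.4, 0.5, 0.9, 1), c(0, 1, 1, 0, 0))
}

#' Evaluate a waveform
#'
#' @param wf A [waveform].
#' @param t Times (s), vectorised.
#' @return Activation values in \[0, 1\] (clamped outside the table).
#' @export
alpha_at <- function(wf, t) {
  stopifnot(inherits(wf, "waveform"))
  approx(wf$t, wf$alpha, xout = t, rule = 2)$y
}

.new_field <- function(gamma, group) {
  stopifnot(all(gamma >= 0), all(gamma <= 1))
  structure(gamma, class = "activation_field", group = group)
}

.require_region <- function(mesh, region, what) {
  if (!any(mesh$region %in% region))
    stop(what, ": mesh has no '", paste(region, collapse = "/"),
         "' region")
}

.require_cols <- function(mesh, cols, what) {
  if (is.null(mesh$elem_data) || !all(cols %in% names(mesh$elem_data)))
    stop(what, ": mesh element data lacks column(s) ",
         paste(cols, collapse = ", "))
}

#' Parasternal intercostal activation field
#'
#' Full activation (`gamma = 1`) at the sternal edge of the parasternal
#' region, decaying linearly to zero in the lateral direction at the
#' costochondral boundary of the region.
#'
#' @param mesh A [tet_mesh] with a `parasternal` region and a `dorsalness`
#'   element coordinate.
#' @return An `activation_field`: per-element gamma vector.
#' @export
parasternal_field <- function(mesh) {
  .require_region(mesh, "parasternal", "parasternal_field")
  .require_cols(mesh, "dorsalness", "parasternal_field")
  g <- numeric(nrow(mesh$tets))
  sel <- mesh$region == "parasternal"
  d <- mesh$elem_data$dorsalness[sel]
  g[sel] <- if (diff(range(d)) > 0) (max(d) - d) / (max(d) - min(d)) else 1
  .new_field(g, "parasternal")
}

#' External intercostal activation field (inspiratory)
#'
#' Separable ramp over the intercostal region: maximal (`gamma = 1`) in the
#' dorsal part of the topmost interspace, decaying toward the ventral side
#' (linear in the dorsalness coordinate) and caudally (interspace weight
#' `((K - k + 1)/K)^power` for interspace `k` of `K`; the default
#' `power = 3` gives the steep craniocaudal electromyographic gradient that
#' makes upper ribs rotate more than lower ones).
#'
#' @param mesh A [tet_mesh] with an `intercostal` region and `dorsalness`
#'   and `interspace` element coordinates.
#' @param power Exponent of the interspace decay (>= 1).
#' @return An `activation_field`.
#' @export
external_intercostal_field <- function(mesh, power = 3) {
  .require_region(mesh, "intercostal", "external_intercostal_field")
  .require_cols(mesh, c("dorsalness", "interspace"),
                "external_intercostal_field")
  g <- numeric(nrow(mesh$tets))
  sel <- mesh$region == "intercostal"
  d <- mesh$elem_data$dorsalness[sel]
  k <- mesh$elem_data$interspace[sel]
  K <- max(k)
  rd <- if (diff(range(d)) > 0) (d - min(d)) / (max(d) - min(d)) else 1
  g[sel] <- rd * ((K - k + 1) / K)^power
  .new_field(g, "external_intercostal")
}

#' Internal intercostal activation field (expiratory)
#'
#' Mirror of [external_intercostal_field()]: maximal in the dorsal part of
#' the lowest interspace, decaying cranially and ventrally.
#'
#' @inheritParams external_intercostal_field
#' @return An `activation_field`.
#' @export
internal_intercostal_field <- function(mesh, power = 3) {
  .require_region(mesh, "intercostal", "internal_intercostal_field")
  .require_cols(mesh, c("dorsalness", "interspace"),
                "internal_intercostal_field")
  g <- numeric(nrow(mesh$tets))
  sel <- mesh$region == "intercostal"
  d <- mesh$elem_data$dorsalness[sel]
  k <- mesh$elem_data$interspace[sel]
  K <- max(k)
  rd <- if (diff(range(d)) > 0) (d - min(d)) / (max(d) - min(d)) else 1
  g[sel] <- rd * (k / K)^power
  .new_field(g, "internal_intercostal")
}

#' Uniform activation field
#'
#' `gamma = 1` on every element carrying a fibre direction (optionally
#' restricted to given region tags); the building block for simple
#' verification problems.
#'
#' @param mesh A [tet_mesh].
#' @param regions Optional character vector of region tags to restrict to.
#' @return An `activation_field`.
#' @export
uniform_field <- function(mesh, regions = NULL) {
  g <- if (is.null(mesh$fiber)) rep(0, nrow(mesh$tets))
    else as.numeric(!is.na(mesh$fiber[, 1]))
  if (!is.null(regions)) g <- g * as.numeric(mesh$region %in% regions)
  .new_field(g, "uniform")
}

#' Diaphragm activation field
#'
#' Uniform full activation over the muscular diaphragm (the central tendon
#' is passive).
#'
#' @param mesh A [tet_mesh] with a `diaphragm` region.
#' @return An `activation_field`.
#' @export
diaphragm_field <- function(mesh) {
  .require_region(mesh, "diaphragm", "diaphragm_field")
  g <- as.numeric(mesh$region == "diaphragm")
  .new_field(g, "diaphragm")
}

#' Scale an activation field by a global level
#'
#' @param field An `activation_field`.
#' @param level Global activation level in \[0, 1\] (e.g. 0.3 for quiet
#'   breathing).
#' @return The scaled `activation_field`.
#' @export
scale_field <- function(field, level) {
  stopifnot(inherits(field, "activation_field"), level >= 0, level <= 1)
  .new_field(as.numeric(field) * level, attr(field, "group"))
}

#' Activation schedule: spatial fields times a temporal waveform
#'
#' @param fields List of `activation_field` objects (non-overlapping muscle
#'   groups; their per-element values are summed and must stay within
#'   \[0, 1\]).
#' @param waveform A [waveform] giving `alpha(t)`.
#' @param span Time span `c(t0, t1)` (s) of the simulation; pressure loads
#'   ramp linearly across it.
#' @return An object of class `activation_schedule`.
#' @export
activation_schedule <- function(fields = list(),
                                waveform = default_breath_waveform(),
                                span = c(0, 1)) {
  stopifnot(inherits(waveform, "waveform"), length(span) == 2L,
            span[2] > span[1])
  gamma <- NULL
  for (f in fields) {
    stopifnot(inherits(f, "activation_field"))
    gamma <- if (is.null(gamma)) as.numeric(f) else gamma + as.numeric(f)
  }
  if (!is.null(gamma) && any(gamma > 1 + 1e-12))
    stop("summed activation fields exceed 1")
  structure(list(fields = fields, gamma = gamma, waveform = waveform,
                 span = span),
            class = "activation_schedule")
}

#' Load and activation state at a time point
#'
#' Evaluates the model's schedule at time `t`: the linear load factor over
#' the schedule span, the temporal activation `alpha(t)`, the per-element
#' activation field, and the pressure magnitude of every pressure load
#' (linear ramp `from -> to`). Times outside the span are clamped with a
#' warning.
#'
#' @param t Time (s).
#' @param model An [fe_model].
#' @return List with `t`, `load_factor`, `alpha`, `gamma`, `pressures`.
#' @export
apply_schedule <- function(t, model) {
  stopifnot(inherits(model, "fe_model"))
  sched <- model$activation
  span <- if (!is.null(sched)) sched$span else c(0, 1)
  if (t < span[1] || t > span[2]) {
    warning(sprintf("time %g outside schedule span [%g, %g]; clamped",
                    t, span[1], span[2]))
    t <- min(max(t, span[1]), span[2])
  }
  lf <- (t - span[1]) / (span[2] - span[1])
  alpha <- if (!is.null(sched)) alpha_at(sched$waveform, t) else 1
  gamma <- if (!is.null(sched) && !is.null(sched$gamma)) sched$gamma
    else numeric(model$setup$n_elems)
  prs <- list()
  for (p in model$pressures)
    prs[[p$face_set]] <- p$from + lf * (p$to - p$from)
  list(t = t, load_factor = lf, alpha = alpha, gamma = gamma,
       pressures = prs)
}
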