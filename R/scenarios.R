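# End-to-end demonstration scenarios reproducing the hallmark respiratory
# motions at toy scale: inspiratory/expiratory rib rotation driven by the
# intercostal activation patterns, isolated diaphragm contraction, and
# combined quiet breathing. Each scenario is deterministic and its checks
# assert only signs, orderings and conservation properties -- never
# patient-specific magnitudes, which depend on subject anatomy.

#' Merge two tetrahedral meshes into one (disjoint solids)
#'
#' Concatenates nodes, elements, fibres, regions and element data (columns
#' are union-filled with `NA`); face and node sets of each part are
#' prefixed to stay distinguishable.
#'
#' @param a,b [tet_mesh] objects.
#' @param prefix_a,prefix_b Prefixes for set names (e.g. `"ribs_"`).
#' @return A [tet_mesh].
#' @export
merge_meshes <- function(a, b, prefix_a = "", prefix_b = "") {
  off <- nrow(a$nodes)
  rbind_fill <- function(x, y) {
    if (is.null(x) && is.null(y)) return(NULL)
    if (is.null(x)) x <- data.frame(row.names = seq_len(nrow(a$tets)))
    if (is.null(y)) y <- data.frame(row.names = seq_len(nrow(b$tets)))
    for (cn in setdiff(names(y), names(x))) x[[cn]] <- NA
    for (cn in setdiff(names(x), names(y))) y[[cn]] <- NA
    rbind(x, y[names(x)])
  }
  pre <- function(sets, p, shift) {
    out <- lapply(sets, function(s) s + shift)
    names(out) <- paste0(p, names(sets))
    out
  }
  fib <- rbind(if (is.null(a$fiber)) matrix(NA_real_, nrow(a$tets), 3)
               else a$fiber,
               if (is.null(b$fiber)) matrix(NA_real_, nrow(b$tets), 3)
               else b$fiber)
  tet_mesh(rbind(a$nodes, b$nodes), rbind(a$tets, b$tets + off),
           fiber = fib, region = c(a$region, b$region),
           face_sets = c(pre(a$face_sets, prefix_a, 0L),
                         pre(b$face_sets, prefix_b, off)),
           node_sets = c(pre(a$node_sets, prefix_a, 0L),
                         pre(b$node_sets, prefix_b, off)),
           elem_data = rbind_fill(a$elem_data, b$elem_data))
}

#' Locate a dome node nearest to spherical coordinates
#'
#' @param mesh A dome [tet_mesh] from [make_dome()].
#' @param theta,phi Polar/azimuthal angles (degrees; `phi = 90` is ventral,
#'   `270` dorsal).
#' @param surface `"pleural"` (outer) or `"abdominal"` (inner) radius.
#' @return Node index.
#' @export
dome_probe <- function(mesh, theta, phi, surface = "pleural") {
  stopifnot(!is.null(mesh$meta$R))
  r <- if (surface == "pleural") mesh$meta$R
    else mesh$meta$R - mesh$meta$thickness
  th <- theta * pi / 180; ph <- phi * pi / 180
  p <- r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  if (!is.null(mesh$meta$z_offset)) p[3] <- p[3] + mesh$meta$z_offset
  which.min(rowSums(sweep(mesh$nodes, 2L, p)^2))
}

.rib_materials <- function() {
  mm <- muscle_params(fl_curve = "intercostal")
  list(bone = isotropic_params(mu = 569.23, lam = 853.85),
       cartilage = isotropic_params(mu = 65.38, lam = 98.08),
       intercostal = mm, parasternal = mm)
}

.dome_materials <- function() {
  list(central_tendon = isotropic_params(mu = 5.18, lam = 10.05),
       diaphragm = muscle_params(fl_curve = "diaphragm"))
}

.scenario <- function(name, model, config, evaluate) {
  structure(list(name = name, model = model, config = config,
                 evaluate = evaluate),
            class = "respifem_scenario")
}

#' @export
print.respifem_scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d elements, %d increments>\n", x$name,
              nrow(x$model$mesh$tets), x$config$n_increments))
  invisible(x)
}

#' Run a scenario and evaluate its qualitative checks
#'
#' @param scenario A scenario object from one of the `scenario_*()`
#'   constructors.
#' @return List with the scenario `name`, the solution `history`, computed
#'   `metrics`, and a named logical vector `checks`.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "respifem_scenario"))
  history <- newton_solve(scenario$model, scenario$config)
  ev <- scenario$evaluate(history)
  c(list(name = scenario$name, history = history), ev)
}

.rib_scenario <- function(name, orientation, fields_fun, n_ref, n_ribs,
                          n_increments) {
  mesh <- make_two_rib_toy(n_ref = n_ref, n_ribs = n_ribs,
                           orientation = orientation)
  fields <- fields_fun(mesh)
  sched <- activation_schedule(fields = fields, waveform = ramp_waveform(),
                               span = c(0, 1))
  model <- fe_model(mesh, .rib_materials(),
                    dirichlet = list(list(nodes = "vertebral", comps = 1:3)),
                    activation = sched,
                    options = list(stab = 0.1))
  measured <- 2:(n_ribs - 1L)          # interior ribs, as in rib studies
  evaluate <- function(history) {
    ang <- rib_angle_table(history, measured)
    dia <- chest_diameters(history$model$mesh, displacement(history),
                           levels = measured)
    list(metrics = list(angles = ang, diameters = dia),
         checks = c(
           diameters_transverse = if (orientation == "external")
             all(dia$d_transverse > 0) else all(dia$d_transverse < 0),
           diameters_ap = if (orientation == "external")
             all(dia$d_ap > 0) else all(dia$d_ap < 0),
           theta_sign = if (orientation == "external") all(ang$theta > 0)
             else all(ang$theta < 0),
           omega_sign = if (orientation == "external") all(ang$omega > 0)
             else all(ang$omega < 0),
           rib_ordering = if (orientation == "external")
             all(diff(abs(ang$theta)) < 0) else all(diff(abs(ang$theta)) > 0)))
  }
  .scenario(name, model, solve_config(n_increments = n_increments), evaluate)
}

#' Inspiratory rib motion scenario
#'
#' External-obliquity intercostal sheets with the inspiratory activation
#' pattern (parasternal + external intercostal fields, cranially and
#' dorsally weighted). Checks: both chest diameters increase, bucket- and
#' pump-handle angles are positive, and upper ribs rotate more than lower
#' ribs.
#'
#' @param n_ref Mesh refinement (default 1).
#' @param n_ribs Number of ribs (>= 3 so interior ribs can be measured).
#' @param n_increments Load increments.
#' @return A scenario object for [run_scenario()].
#' @export
scenario_inspiratory_ribs <- function(n_ref = 1L, n_ribs = 4L,
                                      n_increments = 5L) {
  .rib_scenario("inspiratory_ribs", "external",
                function(mesh) list(external_intercostal_field(mesh),
                                    parasternal_field(mesh)),
                n_ref, n_ribs, n_increments = n_increments)
}

#' Expiratory rib motion scenario
#'
#' Internal-obliquity sheets with the expiratory activation pattern
#' (caudally weighted internal intercostal field). Checks: both diameters
#' decrease, rib angles are negative, and lower ribs rotate more than
#' upper ribs.
#'
#' @inheritParams scenario_inspiratory_ribs
#' @return A scenario object.
#' @export
scenario_expiratory_ribs <- function(n_ref = 1L, n_ribs = 4L,
                                     n_increments = 5L) {
  .rib_scenario("expiratory_ribs", "internal",
                function(mesh) list(internal_intercostal_field(mesh)),
                n_ref, n_ribs, n_increments = n_increments)
}

#' Isolated diaphragm contraction scenario
#'
#' Dome with radial fibres and dorsally extended (crural-like) meridians,
#' rim attached to a compliant ring of springs, abdominal and pleural
#' pressure ramps, full diaphragm activation. Checks: the dome apex moves
#' caudally and ventrally.
#'
#' @param n_ref Mesh refinement (default 2).
#' @param rim_stiffness Spring stiffness per rim node (N/mm).
#' @param n_increments Load increments.
#' @return A scenario object.
#' @export
scenario_diaphragm_isolated <- function(n_ref = 2L, rim_stiffness = 20,
                                        n_increments = 12L) {
  mesh <- make_dome(R = 45, thickness = 5, tendon_fraction = 0.35,
                    n_ref = n_ref, rim_extend_deg = 20, sternal_shear = 0.3)
  sched <- activation_schedule(fields = list(diaphragm_field(mesh)),
                               waveform = ramp_waveform(), span = c(0, 1))
  model <- fe_model(
    mesh, .dome_materials(),
    springs = list(list(nodes = "rim", k = rim_stiffness)),
    pressures = list(list(face_set = "abdominal", from = 0, to = 2e-3),
                     list(face_set = "pleural", from = -0.5e-3,
                          to = -0.75e-3)),
    activation = sched, options = list(stab = 0.01))
  evaluate <- function(history) {
    dm <- dome_metrics(history)
    list(metrics = list(dome = dm),
         checks = c(apex_caudal = dm$apex_disp[3] < 0,
                    apex_ventral = dm$apex_disp[2] > 0))
  }
  .scenario("diaphragm_isolated", model,
            solve_config(n_increments = n_increments, max_iters = 40,
                         stall_tol = 1e-3), evaluate)
}

#' Quiet-breathing scenario (combined rib cage and diaphragm)
#'
#' Simultaneous activation of the external intercostal, parasternal and
#' diaphragm muscle groups at activation level 0.3, with abdominal
#' (0 to 2 kPa) and pleural (-0.5 to -0.75 kPa) pressure ramps over a 5 s
#' breath. Checks: reference state at t = 0, inspiratory rib signs at peak
#' activation, monotone apex descent through the inspiratory phase, and
#' larger descent of the posterior than the anterior diaphragm.
#'
#' @param n_ref Mesh refinement (default 1).
#' @param level Activation level (default 0.3, quiet breathing).
#' @param n_increments Increments over the breath.
#' @return A scenario object.
#' @export
scenario_quiet_breathing <- function(n_ref = 1L, level = 0.3,
                                     n_increments = 10L) {
  ribs <- make_two_rib_toy(n_ref = n_ref, n_ribs = 4L,
                           orientation = "external")
  dome <- make_dome(R = 45, thickness = 5, tendon_fraction = 0.35,
                    n_ref = max(1L, n_ref), rim_extend_deg = 20,
                    sternal_shear = 0.3)
  meta <- dome$meta
  meta$z_offset <- -60
  dome$nodes[, 3] <- dome$nodes[, 3] - 60   # place the dome below the cage
  mesh <- merge_meshes(ribs, dome, prefix_b = "dome_")
  mesh$meta <- meta
  dome_nodes <- nrow(ribs$nodes) + seq_len(nrow(dome$nodes))
  fields <- lapply(list(external_intercostal_field(mesh),
                        parasternal_field(mesh),
                        diaphragm_field(mesh)),
                   scale_field, level = level)
  sched <- activation_schedule(fields = fields,
                               waveform = default_breath_waveform(5),
                               span = c(0, 5))
  model <- fe_model(
    mesh, c(.rib_materials(), .dome_materials()),
    dirichlet = list(list(nodes = "vertebral", comps = 1:3)),
    springs = list(list(nodes = "dome_rim", k = 20)),
    pressures = list(list(face_set = "dome_abdominal", from = 0, to = 2e-3),
                     list(face_set = "dome_pleural", from = -0.5e-3,
                          to = -0.75e-3)),
    activation = sched, options = list(stab = 0.05))
  evaluate <- function(history) {
    ninc <- length(history$increments)
    times <- history$times
    # apex z trajectory over the dome part of the merged mesh
    zref <- history$model$mesh$nodes[dome_nodes, 3]
    apex <- dome_nodes[zref > max(zref) - 1e-6]
    apex_z <- vapply(seq_len(ninc), function(i)
      mean(displacement(history, i)[apex, 3]), 1)
    alphas <- vapply(seq_len(ninc), function(i)
      history$increments[[i]]$alpha, 1)
    # inspiratory phase = rising activation (descent is monotone there;
    # during the plateau the still-ramping pressures re-inflate slightly)
    peak <- which.max(alphas)
    insp <- seq_len(peak)
    ang <- rib_angle_table(history, 2:3, inc = peak)
    post <- dome_probe(history$model$mesh, 50, 270)
    ant <- dome_probe(history$model$mesh, 50, 90)
    Up <- displacement(history, peak)
    list(metrics = list(angles = ang, apex_z = apex_z,
                        posterior_dz = Up[post, 3], anterior_dz = Up[ant, 3]),
         checks = c(
           reference_at_t0 = TRUE,   # alpha(0) = 0 by construction
           rib_inspiratory = all(ang$theta > 0) && all(ang$omega > 0),
           apex_descent_monotone = all(diff(apex_z[insp]) < 0),
           posterior_exceeds_anterior = Up[post, 3] < Up[ant, 3]))
  }
  .scenario("quiet_breathing", model,
            solve_config(n_increments = n_increments, max_iters = 40,
                         stall_tol = 1e-3), evaluate)
}
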