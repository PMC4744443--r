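# YAML run configurations and the material-point driver: the glue between
# the package API and the command-line interface. A run configuration
# describes mesh generation (or a mesh file), material assignment,
# boundary conditions, loads, activation and solver settings.

#' Build a material from a configuration list
#'
#' @param config List with `model` (`"muscle"` or `"isotropic"`) and the
#'   corresponding parameter fields ([muscle_params()] /
#'   [isotropic_params()]); a muscle `fl_curve` may be an identifier or a
#'   `table` with `lambda` and `value` vectors.
#' @return A `material_params` object.
#' @export
material_from_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$model))
  if (config$model == "isotropic")
    return(isotropic_params(mu = config$mu, lam = config$lam))
  if (config$model != "muscle") stop("unknown material model: ", config$model)
  fl <- config$fl_curve
  if (is.list(fl)) fl <- fl_from_table(fl$lambda, fl$value)
  if (is.null(fl)) fl <- "intercostal"
  args <- config[intersect(names(config),
                           c("T0M", "a", "A", "c", "b", "fl_smooth"))]
  do.call(muscle_params, c(args, list(fl_curve = fl)))
}

#' Load a run configuration and build the model
#'
#' The YAML layout mirrors [fe_model()]: a `mesh` section (`generator` +
#' `args`, or `file`), `materials` (region tag to material spec, see
#' [material_from_config()]), optional `dirichlet`, `pressures`, `springs`,
#' `activation` (`fields`: list of `{type, level}` with type one of
#' `parasternal`, `external_intercostal`, `internal_intercostal`,
#' `diaphragm`; `waveform`: `{t, alpha}` table or `{type: ramp|breath}`;
#' `span`), `options` and `solver` sections.
#'
#' @param path YAML file path.
#' @return List with the assembled `model` and a [solve_config()] built
#'   from the `solver` section.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$mesh), !is.null(cfg$materials))
  mesh <- if (!is.null(cfg$mesh$file)) {
    read_mesh(file.path(dirname(path), cfg$mesh$file))
  } else {
    gen <- match.arg(cfg$mesh$generator,
                     c("strip", "dome", "two_rib_toy"))
    fun <- switch(gen, strip = make_strip, dome = make_dome,
                  two_rib_toy = make_two_rib_toy)
    do.call(fun, if (is.null(cfg$mesh$args)) list() else cfg$mesh$args)
  }
  materials <- lapply(cfg$materials, material_from_config)
  activation <- NULL
  if (!is.null(cfg$activation)) {
    fields <- lapply(cfg$activation$fields, function(f) {
      fld <- switch(match.arg(f$type, c("parasternal",
                                        "external_intercostal",
                                        "internal_intercostal",
                                        "diaphragm", "uniform")),
                    parasternal = parasternal_field(mesh),
                    external_intercostal = external_intercostal_field(mesh),
                    internal_intercostal = internal_intercostal_field(mesh),
                    diaphragm = diaphragm_field(mesh),
                    uniform = uniform_field(mesh, f$regions))
      if (!is.null(f$level)) fld <- scale_field(fld, f$level)
      fld
    })
    span <- if (!is.null(cfg$activation$span))
      as.numeric(cfg$activation$span) else c(0, 1)
    wf <- cfg$activation$waveform
    wf <- if (is.null(wf)) ramp_waveform(span)
      else if (!is.null(wf$type) && wf$type == "ramp") ramp_waveform(span)
      else if (!is.null(wf$type) && wf$type == "breath")
        default_breath_waveform(span[2] - span[1])
      else waveform(wf$t, wf$alpha)
    activation <- activation_schedule(fields = fields, waveform = wf,
                                      span = span)
  }
  as_list <- function(x) if (is.null(x)) list() else x
  model <- fe_model(mesh, materials,
                    dirichlet = as_list(cfg$dirichlet),
                    pressures = as_list(cfg$pressures),
                    springs = as_list(cfg$springs),
                    activation = activation,
                    options = as_list(cfg$options))
  config <- do.call(solve_config,
                    if (is.null(cfg$solver)) list() else cfg$solver)
  list(model = model, config = config)
}

#' Run a configured simulation and write its outputs
#'
#' Solves the model described by a YAML run configuration and writes one
#' VTU snapshot per increment (mesh + displacement) plus a `metrics.json`
#' summary (times, load factors, activation, iteration counts, volume
#' ratios).
#'
#' @param path Run configuration (YAML).
#' @param out_dir Output directory (created if missing).
#' @return The `solution_history`, invisibly.
#' @export
run_simulation <- function(path, out_dir = "respifem_out") {
  rc <- load_run_config(path)
  history <- newton_solve(rc$model, rc$config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- rc$model$mesh
  for (i in seq_along(history$increments)) {
    write_mesh(mesh, file.path(out_dir, sprintf("state_%03d.vtu", i)),
               format = "vtu",
               point_data = list(displacement = displacement(history, i)))
  }
  summary <- lapply(history$increments, function(r)
    list(t = r$t, load_factor = r$load_factor, alpha = r$alpha,
         iterations = r$iterations, stalled = isTRUE(r$stalled),
         max_abs_vol_err = if (all(is.na(r$detC))) NA
           else max(abs(r$detC - 1), na.rm = TRUE)))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(summary, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    saveRDS(summary, file.path(out_dir, "metrics.rds"))
  }
  invisible(history)
}

#' Material-point driver
#'
#' Evaluates the muscle law along a prescribed deformation-gradient
#' history: for each `F`, the reduced fibre stretch, the passive and
#' active fibre stresses, the strain energy and the components of the
#' second Piola-Kirchhoff stress (at the given hydrostatic pressure).
#'
#' @param params A [muscle_params()] object.
#' @param F_list List of 3x3 deformation gradients, or a numeric vector of
#'   fibre stretches (interpreted as isochoric uniaxial states along `N`).
#' @param N Reference fibre direction.
#' @param act An [activation_point()].
#' @param p_hydro Hydrostatic pressure (MPa).
#' @return Data frame with one row per state: `lam_f_bar`, `T_PE`, `T_CE`,
#'   `energy` and the six stress components.
#' @export
matpoint_table <- function(params, F_list, N = c(1, 0, 0),
                           act = activation_point(), p_hydro = 0) {
  stopifnot(inherits(params, "muscle_params"))
  if (is.numeric(F_list) && is.null(dim(F_list)))
    F_list <- lapply(F_list, function(l) diag(c(l, 1 / sqrt(l),
                                                1 / sqrt(l))))
  rows <- lapply(F_list, function(F) {
    kin <- kinematic_state(F, N)
    S <- pk2_stress_muscle(kin, p_hydro, params, act)
    lb <- kin$lam_f_bar
    data.frame(lam_f_bar = lb,
               T_PE = params$T0M * f_pe(lb, params$a, params$A),
               T_CE = params$T0M * fl_eval(params$fl, lb) *
                 act$gamma * act$alpha,
               energy = strain_energy(kin, params, act),
               S11 = S[1, 1], S22 = S[2, 2], S33 = S[3, 3],
               S12 = S[1, 2], S13 = S[1, 3], S23 = S[2, 3])
  })
  do.call(rbind, rows)
}

#' Tabulate the shipped force-length and activation curves
#'
#' @param lam Stretch grid.
#' @param waveform_times Time grid for the default breath waveform.
#' @return Data frame with `lambda`, `f_ce_intercostal`, `f_ce_diaphragm`,
#'   `f_pe` (at the default passive constants), and an attached
#'   `data.frame` attribute `alpha` with the default waveform.
#' @export
curve_table <- function(lam = seq(0.5, 1.3, by = 0.005),
                        waveform_times = seq(0, 5, by = 0.05)) {
  mp <- muscle_params()
  out <- data.frame(lambda = lam,
                    f_ce_intercostal = f_ce_intercostal(lam),
                    f_ce_diaphragm = f_ce_diaphragm(lam),
                    f_pe = f_pe(lam, mp$a, mp$A))
  attr(out, "alpha") <- data.frame(
    t = waveform_times,
    alpha = alpha_at(default_breath_waveform(5), waveform_times))
  out
}
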