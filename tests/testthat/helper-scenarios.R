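# Scenario runs are the most expensive fixtures in the suite; run each one
# once per session and share the result between the scenario tests and the
# acceptance checks.

.scenario_cache <- new.env(parent = emptyenv())

scenario_result <- function(name) {
  if (!exists(name, envir = .scenario_cache)) {
    sc <- switch(name,
                 inspiratory = scenario_inspiratory_ribs(),
                 expiratory = scenario_expiratory_ribs(),
                 diaphragm = scenario_diaphragm_isolated(),
                 quiet = scenario_quiet_breathing(),
                 stop("unknown scenario fixture: ", name))
    assign(name, run_scenario(sc), envir = .scenario_cache)
  }
  get(name, envir = .scenario_cache)
}

# dome-against-rigid-cap contact fixture: the activated dome descends onto
# a rigid spherical cap below its inner surface; cached like the scenarios
contact_dome_result <- function() {
  if (!exists("contact_dome", envir = .scenario_cache)) {
    mesh <- make_dome(R = 45, thickness = 5, tendon_fraction = 0.35,
                      n_ref = 2)
    cap <- make_cap_surface(R = 34, center = c(0, 0, 0), theta_max = 60,
                            n_ref = 3, normal = "outward")
    r <- sqrt(rowSums(mesh$nodes^2))
    slave <- which(abs(r - 40) < 1e-6 & mesh$nodes[, 3] > 0.5 * 40)
    sched <- activation_schedule(fields = list(diaphragm_field(mesh)),
                                 waveform = ramp_waveform(), span = c(0, 1))
    model <- fe_model(
      mesh, list(central_tendon = isotropic_params(5.18, 10.05),
                 diaphragm = muscle_params(fl_curve = "diaphragm")),
      springs = list(list(nodes = "rim", k = 20)),
      contact = list(contact_pair(slave, cap)),
      activation = sched, options = list(stab = 0.01))
    h <- newton_solve(model, solve_config(n_increments = 10, max_iters = 40,
                                          stall_tol = 1e-3))
    assign("contact_dome", list(history = h, model = model, cap = cap,
                                slave = slave),
           envir = .scenario_cache)
  }
  get("contact_dome", envir = .scenario_cache)
}
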