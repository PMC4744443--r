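# Incremental-static Newton solution of the assembled nonlinear system,
# with backtracking line search, step rejection on element inversion, and
# an active-set treatment of the contact KKT conditions: nodes whose gap
# closes enter the active set, nodes whose multiplier turns tensile leave
# it; active multipliers are solved monolithically with displacements and
# incompressibility multipliers.

#' Linear ramp waveform
#'
#' `alpha(t)` rising linearly from 0 to 1 over `span`, the natural choice
#' for incremental quasi-static activation problems.
#'
#' @param span Time span `c(t0, t1)`.
#' @return A [waveform].
#' @export
ramp_waveform <- function(span = c(0, 1)) waveform(span, c(0, 1))

#' Solver configuration
#'
#' @param n_increments Number of load/activation increments (>= 1).
#' @param newton_tol Relative residual tolerance (w.r.t. the first residual
#'   of each increment).
#' @param newton_abs_tol Absolute residual floor (N).
#' @param max_iters Maximum Newton iterations per increment.
#' @param line_search Backtracking line search on the residual norm.
#' @param max_halvings Maximum step halvings in the line search.
#' @param max_active_set_iters Maximum contact active-set updates per
#'   increment.
#' @param stall_tol Absolute force residual (N) below which an iterate is
#'   accepted when the line search can no longer reduce the residual. The
#'   piecewise-linear force-length curves make the equations non-smooth at
#'   their breakpoints, where Newton can stall at a tiny but irreducible
#'   residual; a `stall_tol` well below the load scale accepts such states
#'   (recorded per increment as `stalled`). The default 0 disables it.
#' @param verbose Print per-iteration diagnostics.
#' @return An object of class `solve_config`.
#' @export
solve_config <- function(n_increments = 10L, newton_tol = 1e-8,
                         newton_abs_tol = 1e-10, max_iters = 30L,
                         line_search = TRUE, max_halvings = 10L,
                         max_active_set_iters = 10L, stall_tol = 0,
                         verbose = FALSE) {
  stopifnot(n_increments >= 1, newton_tol > 0, newton_abs_tol > 0,
            max_iters >= 1, stall_tol >= 0)
  structure(list(n_increments = as.integer(n_increments),
                 newton_tol = newton_tol, newton_abs_tol = newton_abs_tol,
                 max_iters = as.integer(max_iters),
                 line_search = isTRUE(line_search),
                 max_halvings = as.integer(max_halvings),
                 max_active_set_iters = as.integer(max_active_set_iters),
                 stall_tol = stall_tol,
                 verbose = isTRUE(verbose)),
            class = "solve_config")
}

# contact bookkeeping: resolve node-set names, initialise multipliers
.init_contact <- function(model) {
  lapply(model$contact, function(cp) {
    nodes <- cp$slave_nodes
    if (is.character(nodes)) nodes <- model$mesh$node_sets[[nodes]]
    list(pair = cp, nodes = as.integer(nodes),
         active = rep(FALSE, length(nodes)),
         eta = numeric(length(nodes)))
  })
}

# residual with contact contributions; returns reduced residual pieces
.contact_residual <- function(model, U, cstate) {
  add <- numeric(3L * nrow(model$mesh$nodes))
  r_eta <- list()
  gaps <- list()
  for (ci in seq_along(cstate)) {
    cs <- cstate[[ci]]
    xcur <- model$mesh$nodes + U
    gp <- .contact_gaps(xcur, cs$nodes, cs$pair$master)
    gaps[[ci]] <- gp
    act <- which(cs$active)
    if (length(act)) {
      for (k in seq_along(act)) {
        i <- act[k]
        dofs <- 3L * (cs$nodes[i] - 1L) + 1:3
        add[dofs] <- add[dofs] + cs$eta[i] * gp$normal[i, ]
      }
      r_eta[[ci]] <- gp$g[act]
    } else r_eta[[ci]] <- numeric(0)
  }
  list(add = add, r_eta = r_eta, gaps = gaps)
}

#' Solve an activated, loaded model by incremental Newton iteration
#'
#' Marches the schedule span in `n_increments` quasi-static increments.
#' Within each increment Newton iterations (with consistent tangent,
#' optional backtracking line search, and rejection of element-inverting
#' steps) run until the reduced residual drops below
#' `max(newton_abs_tol, newton_tol * first residual)`; the contact active
#' set is updated between Newton solves until it is stable. Non-convergence
#' raises an error of class `respifem_nonconvergence` carrying the history
#' so far in its `history` field.
#'
#' @param model An [fe_model].
#' @param config A [solve_config()].
#' @return A `solution_history`: list with `times`, per-increment states
#'   (`u` as an `n x 3` matrix, `xi`, hydrostatic pressures `p = -2 xi`,
#'   per-element volume ratios `detC`, contact state, iteration counts) and
#'   the generating `model`.
#' @export
newton_solve <- function(model, config = solve_config()) {
  stopifnot(inherits(model, "fe_model"), inherits(config, "solve_config"))
  s <- model$setup
  n3 <- 3L * s$n_nodes
  free_u <- which(!s$fixed)
  xi_dofs <- n3 + seq_len(s$n_xi)
  u <- numeric(n3)
  xi <- numeric(s$n_xi)
  cstate <- .init_contact(model)
  span <- if (!is.null(model$activation)) model$activation$span else c(0, 1)
  times <- seq(span[1], span[2], length.out = config$n_increments + 1L)[-1L]
  history <- list()
  fail <- function(msg, inc, rnorm) {
    h <- .finish_history(history, model, times, converged = FALSE)
    cond <- structure(
      list(message = sprintf(
        "no convergence at increment %d (t = %g): %s (residual %.3e)",
        inc, times[inc], msg, rnorm),
        call = sys.call(-1), history = h),
      class = c("respifem_nonconvergence", "error", "condition"))
    stop(cond)
  }
  for (inc in seq_along(times)) {
    state <- apply_schedule(times[inc], model)
    # impose prescribed displacement values
    for (d in model$dirichlet) {
      fac <- if (d$ramp) state$load_factor else 1
      if (is.matrix(d$value)) {
        # per-node prescribed values: rows follow d$nodes, cols follow d$comps
        for (ic in seq_along(d$comps))
          u[3L * (d$nodes - 1L) + d$comps[ic]] <- fac * d$value[, ic]
      } else {
        val <- rep_len(d$value, length(d$comps)) * fac
        for (ic in seq_along(d$comps))
          u[3L * (d$nodes - 1L) + d$comps[ic]] <- val[ic]
      }
    }
    iters_total <- 0L
    res_norms <- numeric(0)
    stalled <- FALSE
    for (as_it in seq_len(config$max_active_set_iters)) {
      conv <- FALSE
      rref <- NA_real_
      for (it in seq_len(config$max_iters)) {
        U <- matrix(u, ncol = 3L, byrow = TRUE)
        asm <- assemble_system(model, u, xi, state, want_K = TRUE)
        if (asm$inverted)
          fail(sprintf("inverted element %d at accepted state",
                       asm$bad_elem), inc, Inf)
        cres <- .contact_residual(model, U, cstate)
        n_act <- vapply(cstate, function(cs) sum(cs$active), 1L)
        res <- asm$res
        res[seq_len(n3)] <- res[seq_len(n3)] + cres$add
        r_red <- c(res[free_u], res[xi_dofs], unlist(cres$r_eta))
        rnorm <- sqrt(sum(r_red^2))
        res_norms <- c(res_norms, rnorm)
        if (it == 1L) rref <- max(rnorm, config$newton_abs_tol)
        if (config$verbose)
          message(sprintf(
            "inc %d as %d it %d: residual %.3e (active contacts %d)",
            inc, as_it, it, rnorm, sum(n_act)))
        if (rnorm < max(config$newton_abs_tol, config$newton_tol * rref)) {
          conv <- TRUE
          break
        }
        # build reduced tangent with contact blocks
        nred <- length(free_u) + s$n_xi + sum(n_act)
        map <- integer(n3 + s$n_xi)
        map[free_u] <- seq_along(free_u)
        map[xi_dofs] <- length(free_u) + seq_len(s$n_xi)
        Kr <- asm$K[c(free_u, xi_dofs), c(free_u, xi_dofs), drop = FALSE]
        if (sum(n_act)) {
          ci_list <- list(); cj_list <- list(); cx_list <- list()
          off <- length(free_u) + s$n_xi
          pos <- 0L
          for (ci in seq_along(cstate)) {
            cs <- cstate[[ci]]
            gp <- cres$gaps[[ci]]
            for (i in which(cs$active)) {
              pos <- pos + 1L
              dofs <- 3L * (cs$nodes[i] - 1L) + 1:3
              md <- map[dofs]
              keep <- md > 0L
              nrm <- gp$normal[i, ]
              ci_list[[pos]] <- c(md[keep], rep(off + pos, sum(keep)))
              cj_list[[pos]] <- c(rep(off + pos, sum(keep)), md[keep])
              cx_list[[pos]] <- c(nrm[keep], nrm[keep])
            }
          }
          Kc <- Matrix::sparseMatrix(i = unlist(ci_list),
                                     j = unlist(cj_list),
                                     x = unlist(cx_list),
                                     dims = c(nred, nred))
          Kfull <- Kc
          Kfull[seq_len(off), seq_len(off)] <-
            Kfull[seq_len(off), seq_len(off)] + Kr
          Kr <- Kfull
        }
        delta <- tryCatch(
          as.numeric(Matrix::solve(Kr, -r_red)),
          error = function(e) fail(paste("linear solve failed:",
                                         conditionMessage(e)), inc, rnorm))
        # split the update
        du <- numeric(n3)
        du[free_u] <- delta[seq_along(free_u)]
        dxi <- delta[length(free_u) + seq_len(s$n_xi)]
        deta <- if (sum(n_act))
          delta[length(free_u) + s$n_xi + seq_len(sum(n_act))] else numeric(0)
        step <- 1
        accepted <- FALSE
        for (half in 0:config$max_halvings) {
          u_try <- u + step * du
          xi_try <- xi + step * dxi
          cs_try <- cstate
          if (length(deta)) {
            pos <- 0L
            for (ci in seq_along(cs_try)) {
              act <- which(cs_try[[ci]]$active)
              for (i in act) {
                pos <- pos + 1L
                cs_try[[ci]]$eta[i] <- cs_try[[ci]]$eta[i] +
                  step * deta[pos]
              }
            }
          }
          asm_try <- assemble_system(model, u_try, xi_try, state,
                                     want_K = FALSE)
          if (!asm_try$inverted) {
            U_try <- matrix(u_try, ncol = 3L, byrow = TRUE)
            cres_try <- .contact_residual(model, U_try, cs_try)
            res_try <- asm_try$res
            res_try[seq_len(n3)] <- res_try[seq_len(n3)] + cres_try$add
            r_try <- c(res_try[free_u], res_try[xi_dofs],
                       unlist(cres_try$r_eta))
            rn_try <- sqrt(sum(r_try^2))
            if (!config$line_search || rn_try < (1 - 1e-4 * step) * rnorm ||
                rn_try < config$newton_abs_tol) {
              u <- u_try; xi <- xi_try; cstate <- cs_try
              accepted <- TRUE
              break
            }
          }
          step <- step / 2
        }
        iters_total <- iters_total + 1L
        if (!accepted) {
          if (rnorm < config$stall_tol) {
            # non-smooth stall at a negligible force residual: accept
            stalled <- TRUE
            conv <- TRUE
            if (config$verbose)
              message(sprintf(
                "inc %d: accepted stalled iterate (residual %.3e)",
                inc, rnorm))
            break
          }
          fail("line search stalled", inc, rnorm)
        }
      }
      if (!conv) {
        if (rnorm < config$stall_tol) {
          stalled <- TRUE
        } else fail("maximum Newton iterations reached", inc, rnorm)
      }
      # active-set update at the converged state
      U <- matrix(u, ncol = 3L, byrow = TRUE)
      changed <- FALSE
      xcur <- model$mesh$nodes + U
      for (ci in seq_along(cstate)) {
        cs <- cstate[[ci]]
        gp <- .contact_gaps(xcur, cs$nodes, cs$pair$master)
        release <- cs$active & cs$eta > 0
        engage <- !cs$active & gp$g < -cs$pair$gap_tol
        if (any(release) || any(engage)) changed <- TRUE
        cs$active[release] <- FALSE
        cs$eta[release] <- 0
        cs$active[engage] <- TRUE
        cstate[[ci]] <- cs
      }
      if (!changed) break
      if (as_it == config$max_active_set_iters)
        fail("contact active set did not settle", inc, NA_real_)
    }
    U <- matrix(u, ncol = 3L, byrow = TRUE)
    xcur <- model$mesh$nodes + U
    contact_rec <- lapply(cstate, function(cs) {
      gp <- .contact_gaps(xcur, cs$nodes, cs$pair$master)
      list(nodes = cs$nodes, active = cs$active, eta = cs$eta, g = gp$g)
    })
    asm <- assemble_system(model, u, xi, state, want_K = FALSE)
    history[[inc]] <- list(t = times[inc], u = U, xi = xi, p = -2 * xi,
                           detC = asm$detC, load_factor = state$load_factor,
                           alpha = state$alpha, pressures = state$pressures,
                           contact = contact_rec, iterations = iters_total,
                           res_norms = res_norms, stalled = stalled)
  }
  .finish_history(history, model, times, converged = TRUE)
}

.finish_history <- function(history, model, times, converged) {
  structure(list(increments = history,
                 times = times[seq_along(history)],
                 model = model, converged = converged),
            class = "solution_history")
}

#' @export
print.solution_history <- function(x, ...) {
  cat(sprintf("<solution_history: %d/%d increments%s>\n",
              length(x$increments), length(x$times),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Displacement field of an increment
#'
#' @param history A `solution_history` from [newton_solve()].
#' @param inc Increment index (default: last).
#' @return `n x 3` displacement matrix (mm).
#' @export
displacement <- function(history, inc = length(history$increments)) {
  stopifnot(inherits(history, "solution_history"),
            inc >= 1, inc <= length(history$increments))
  history$increments[[inc]]$u
}

#' Reaction forces on a node set
#'
#' The assembled internal-minus-external residual restricted to constrained
#' nodes equals the reaction the supports exert; this evaluates it at a
#' stored increment.
#'
#' @param history A `solution_history`.
#' @param nodes Node indices or node-set name.
#' @param inc Increment index (default: last).
#' @return `length(nodes) x 3` matrix of reaction forces (N).
#' @export
reaction_forces <- function(history, nodes,
                            inc = length(history$increments)) {
  model <- history$model
  if (is.character(nodes)) nodes <- model$mesh$node_sets[[nodes]]
  rec <- history$increments[[inc]]
  state <- apply_schedule(rec$t, model)
  asm <- assemble_system(model, as.vector(t(rec$u)), rec$xi, state,
                         want_K = FALSE)
  out <- matrix(asm$res[as.vector(t(cbind(3L * (nodes - 1L) + 1L,
                                          3L * (nodes - 1L) + 2L,
                                          3L * nodes)))],
                ncol = 3L, byrow = TRUE)
  rownames(out) <- as.character(nodes)
  out
}
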