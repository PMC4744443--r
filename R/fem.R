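# Mixed displacement-pressure tetrahedral discretisation. Each node carries
# three displacement DOFs; each incompressible (muscle) element carries one
# constant multiplier DOF xi enforcing det(C) = 1 in the weak sense, the
# P1-P0 reading of "three displacement nodes and one hydrostatic pressure
# node". The multiplier relates to the hydrostatic pressure by p = -2 xi.
# Single-point quadrature (exact for constant-strain tetrahedra).

#' Finite-element model of an actively contracting tissue assembly
#'
#' Binds a mesh to materials, boundary conditions, loads, activation and
#' contact, ready for [newton_solve()].
#'
#' @param mesh A [tet_mesh].
#' @param materials Named list mapping region tags to [muscle_params()] /
#'   [isotropic_params()] objects. Muscle regions are treated as
#'   incompressible (element multiplier DOF); isotropic regions are
#'   compressible Saint Venant-Kirchhoff.
#' @param dirichlet List of constraints `list(nodes=, comps=, value=,
#'   ramp=)`: node indices (or the name of a node set), constrained
#'   components (subset of 1:3), prescribed values (scalar, one value per
#'   component, or a `length(nodes) x length(comps)` matrix; default 0) and
#'   whether the value scales with the load factor (default `TRUE`).
#' @param pressures List of follower pressure loads `list(face_set=, from=,
#'   to=)` in MPa; magnitude ramps linearly with schedule time. Positive
#'   magnitudes push into the solid (traction `-q n` on the outward normal
#'   `n`), so a positive abdominal pressure inflates a dome from below and a
#'   negative pleural pressure applies suction.
#' @param springs List of `list(nodes=, k=)`: linear restoring springs to
#'   the reference position (N/mm per node), for compliant attachments.
#' @param contact List of [contact_pair()] objects.
#' @param activation An [activation_schedule()] or `NULL`.
#' @param options List: `follower` (default `TRUE`; `FALSE` evaluates
#'   pressure loads on the reference surface, for testing), `stab`
#'   (perturbed-Lagrangian regularisation of the element multipliers,
#'   MPa^-1 scale; see the methods vignette).
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(mesh, materials, dirichlet = list(), pressures = list(),
                     springs = list(), contact = list(), activation = NULL,
                     options = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  miss <- setdiff(unique(mesh$region), names(materials))
  if (length(miss))
    stop("no material assigned to region(s): ", paste(miss, collapse = ", "))
  opts <- modifyList(list(follower = TRUE, stab = 1e-3), options)
  dirichlet <- lapply(dirichlet, function(d) {
    if (is.character(d$nodes)) d$nodes <- mesh$node_sets[[d$nodes]]
    if (is.null(d$nodes) || !length(d$nodes))
      stop("dirichlet constraint with empty node set")
    if (is.null(d$comps)) d$comps <- 1:3
    if (is.null(d$value)) d$value <- 0
    if (is.null(d$ramp)) d$ramp <- TRUE
    d
  })
  springs <- lapply(springs, function(s) {
    if (is.character(s$nodes)) s$nodes <- mesh$node_sets[[s$nodes]]
    stopifnot(length(s$nodes) > 0, s$k >= 0)
    s
  })
  for (p in pressures)
    if (is.null(mesh$face_sets[[p$face_set]]))
      stop("pressure load references unknown face set '", p$face_set, "'")
  m <- structure(list(mesh = mesh, materials = materials,
                      dirichlet = dirichlet, pressures = pressures,
                      springs = springs, contact = contact,
                      activation = activation, options = opts),
                 class = "fe_model")
  m$setup <- .model_setup(m)
  m
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model: %d nodes, %d tets (%d incompressible), %d pressure load(s), %d contact pair(s)>\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tets),
              sum(x$setup$is_muscle), length(x$pressures),
              length(x$contact)))
  invisible(x)
}

# precompute shape gradients, volumes, DOF maps, per-element material refs
.model_setup <- function(model) {
  mesh <- model$mesh
  m <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  G <- vector("list", m)
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$tets[e, ], ]
    De <- t(X[2:4, ] - rep(X[1, ], each = 3L))   # columns X_a - X_1
    Dinv <- solve(De)                            # local coords xi = Dinv (X - X1)
    Ge <- rbind(-colSums(Dinv), Dinv)            # 4x3, rows = grad N_a
    G[[e]] <- Ge
  }
  mat <- model$materials[mesh$region]
  is_muscle <- vapply(mat, inherits, TRUE, what = "muscle_params")
  xi_id <- integer(m)
  xi_id[is_muscle] <- seq_len(sum(is_muscle))
  # fixed (Dirichlet) dof bookkeeping
  fixed <- rep(FALSE, 3L * n)
  for (d in model$dirichlet)
    for (cmp in d$comps) fixed[3L * (d$nodes - 1L) + cmp] <- TRUE
  list(G = G, V = mesh$volumes, mat = mat, is_muscle = is_muscle,
       xi_id = xi_id, n_xi = sum(is_muscle), n_nodes = n, n_elems = m,
       fixed = fixed)
}

# deformation gradient of one element; Ue is 4x3 nodal displacements
.elem_F <- function(Ge, Ue) diag(3) + t(Ue) %*% Ge

#' Element kinematics from a global displacement vector
#'
#' Constant-per-element deformation measures of the linear tetrahedron:
#' `F = I + du/dX`, `C = t(F) F`, `J = det F`, plus the reduced invariants
#' via [kinematic_state()].
#'
#' @param mesh A [tet_mesh].
#' @param elem_id Element index.
#' @param u Global displacement vector (length `3 * n_nodes`) or `n x 3`
#'   matrix.
#' @return A [kinematic_state] (fibre direction attached when the element
#'   has one); elements with `det F <= 0` raise an error flagging inversion.
#' @export
element_kinematics <- function(mesh, elem_id, u) {
  stopifnot(inherits(mesh, "tet_mesh"))
  U <- .as_disp_matrix(u, nrow(mesh$nodes))
  X <- mesh$nodes[mesh$tets[elem_id, ], ]
  De <- t(X[2:4, ] - rep(X[1, ], each = 3L))
  Dinv <- solve(De)
  Ge <- rbind(-colSums(Dinv), Dinv)
  F <- .elem_F(Ge, U[mesh$tets[elem_id, ], , drop = FALSE])
  if (det(F) <= 0)
    stop("inverted element ", elem_id, " (det F <= 0)")
  N <- if (!is.null(mesh$fiber) && !is.na(mesh$fiber[elem_id, 1]))
    mesh$fiber[elem_id, ] else NULL
  kinematic_state(F, N)
}

.as_disp_matrix <- function(u, n) {
  if (is.matrix(u)) {
    stopifnot(nrow(u) == n, ncol(u) == 3L)
    u
  } else {
    stopifnot(length(u) == 3L * n)
    matrix(u, ncol = 3L, byrow = TRUE)
  }
}

# strain-displacement matrix (6x12, engineering shear) for current F
.elem_B <- function(F, Ge) {
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- Ge[a, ]
    cols <- (3L * (a - 1L) + 1L):(3L * a)
    B[1, cols] <- F[, 1] * g[1]
    B[2, cols] <- F[, 2] * g[2]
    B[3, cols] <- F[, 3] * g[3]
    B[4, cols] <- F[, 1] * g[2] + F[, 2] * g[1]
    B[5, cols] <- F[, 1] * g[3] + F[, 3] * g[1]
    B[6, cols] <- F[, 2] * g[3] + F[, 3] * g[2]
  }
  B
}

# core element computation: residual contributions and (optionally) tangent.
# Returns NULL if the element is inverted.
.elem_core <- function(Ge, Ve, mat, is_mus, N, xi_e, ga, stab,
                       Ue, want_K = TRUE) {
  F <- .elem_F(Ge, Ue)
  detF <- det(F)
  if (!is.finite(detF) || detF <= 0) return(NULL)
  C <- crossprod(F)
  if (is_mus) {
    Ci <- chol2inv(chol(C))
    detC <- detF^2
    res <- .muscle_S_dev(C, Ci, detC, N, mat, ga)
    S <- res$S + .vol_S(Ci, detC, xi_e)
    r_xi <- Ve * (detC - 1) - stab * Ve * xi_e
    jv <- .sv(.vol_S(Ci, detC, 1))         # dS/dxi = 2 detC Ci
  } else {
    S <- .svk_S(C, mat)
    r_xi <- NULL
    jv <- NULL
  }
  B <- .elem_B(F, Ge)
  Sv <- .sv(S)
  f <- Ve * drop(crossprod(B, Sv))
  out <- list(f = f, r_xi = r_xi, detC = detF^2,
              energy_ok = TRUE)
  if (want_K) {
    D <- if (is_mus)
      .muscle_D_dev(C, Ci, detC, N, mat, ga) + .vol_D(Ci, detC, xi_e)
    else .svk_D(mat)
    K <- Ve * (crossprod(B, D %*% B))
    Gs <- Ve * (Ge %*% S %*% t(Ge))        # geometric part, 4x4
    for (a in 1:4) for (b in 1:4) {
      ia <- 3L * (a - 1L); ib <- 3L * (b - 1L)
      K[ia + 1L, ib + 1L] <- K[ia + 1L, ib + 1L] + Gs[a, b]
      K[ia + 2L, ib + 2L] <- K[ia + 2L, ib + 2L] + Gs[a, b]
      K[ia + 3L, ib + 3L] <- K[ia + 3L, ib + 3L] + Gs[a, b]
    }
    out$K <- K
    if (is_mus) {
      out$k_uxi <- Ve * drop(crossprod(B, jv))
      out$k_xixi <- -stab * Ve
    }
  }
  out
}

#' Element residual of the mixed formulation
#'
#' The internal-force contribution of one element: 12 displacement entries
#' (the gradient of the element energy plus the multiplier term
#' `xi * dU_V/dE` with `U_V = det C - 1`) and, for incompressible muscle
#' elements, one constraint entry `integral(det C - 1) dV`.
#'
#' @param model An [fe_model].
#' @param elem_id Element index.
#' @param u Global displacement vector or `n x 3` matrix.
#' @param xi Element multiplier (ignored for compressible regions).
#' @param alpha Temporal activation scaling the element's gamma.
#' @param gamma Activation level override (default: the element's field
#'   value is not used here; pass the desired gamma).
#' @return List with `f` (12-vector, N) and `r_xi` (scalar, mm^3, or `NULL`).
#' @export
element_residual <- function(model, elem_id, u, xi = 0, alpha = 1,
                             gamma = 0) {
  stopifnot(inherits(model, "fe_model"))
  s <- model$setup
  U <- .as_disp_matrix(u, s$n_nodes)
  Ue <- U[model$mesh$tets[elem_id, ], , drop = FALSE]
  N <- if (!is.null(model$mesh$fiber) && !is.na(model$mesh$fiber[elem_id, 1]))
    model$mesh$fiber[elem_id, ] else NULL
  out <- .elem_core(s$G[[elem_id]], s$V[elem_id], s$mat[[elem_id]],
                    s$is_muscle[elem_id], N, xi, alpha * gamma,
                    model$options$stab, Ue, want_K = FALSE)
  if (is.null(out)) stop("inverted element ", elem_id)
  out[c("f", "r_xi")]
}

#' Follower pressure load vector
#'
#' Consistent nodal forces of a uniform pressure on a face set, integrated
#' over the deformed surface (follower load): each triangle contributes
#' `-q/6 * (x2-x1) x (x3-x1)` to each of its nodes, where `x` are current
#' positions. With `follower = FALSE` the reference geometry is used (dead
#' load).
#'
#' @param mesh A [tet_mesh].
#' @param face_set Face-set name.
#' @param magnitude Pressure (MPa); positive pushes against the outward
#'   normal (into the solid).
#' @param u Global displacement vector or matrix (default zero).
#' @param follower Evaluate on the deformed configuration (default `TRUE`).
#' @return Global load vector (length `3 * n_nodes`, N).
#' @export
pressure_load_residual <- function(mesh, face_set, magnitude, u = NULL,
                                   follower = TRUE) {
  stopifnot(inherits(mesh, "tet_mesh"))
  faces <- mesh$face_sets[[face_set]]
  if (is.null(faces)) stop("no face set named '", face_set, "'")
  n <- nrow(mesh$nodes)
  U <- if (is.null(u)) matrix(0, n, 3) else .as_disp_matrix(u, n)
  x <- mesh$nodes + if (follower) U else 0
  f <- numeric(3L * n)
  for (i in seq_len(nrow(faces))) {
    v <- faces[i, ]
    e1 <- x[v[2], ] - x[v[1], ]
    e2 <- x[v[3], ] - x[v[1], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    fn <- -magnitude / 6 * cr
    for (a in 1:3) {
      ix <- 3L * (v[a] - 1L)
      f[ix + 1:3] <- f[ix + 1:3] + fn
    }
  }
  f
}

.skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1],
                              v[2], -v[1], 0), 3, 3)

# triplet contributions of the follower-pressure load tangent dR/du = -df/du
.pressure_tangent_triplets <- function(mesh, face_set, magnitude, U) {
  faces <- mesh$face_sets[[face_set]]
  x <- mesh$nodes + U
  nf <- nrow(faces)
  ii <- integer(81L * nf); jj <- integer(81L * nf); xx <- numeric(81L * nf)
  pos <- 0L
  for (i in seq_len(nf)) {
    v <- faces[i, ]
    a <- x[v[2], ] - x[v[1], ]
    b <- x[v[3], ] - x[v[1], ]
    dc <- list(.skew(b) - .skew(a), -.skew(b), .skew(a)) # d cross /d x1,2,3
    for (na in 1:3) for (nm in 1:3) {
      blk <- (magnitude / 6) * dc[[nm]]   # -d f_a/d x_m = +q/6 dc/dx_m
      rows <- 3L * (v[na] - 1L) + 1:3
      cols <- 3L * (v[nm] - 1L) + 1:3
      ii[pos + 1:9] <- rep(rows, 3L)
      jj[pos + 1:9] <- rep(cols, each = 3L)
      xx[pos + 1:9] <- as.vector(blk)
      pos <- pos + 9L
    }
  }
  list(i = ii, j = jj, x = xx)
}

#' Assemble the global mixed system
#'
#' Scatter-adds element residuals and tangents, applies pressure, spring and
#' activation terms, and returns the assembled residual and sparse tangent
#' over the DOF layout `[3 * n_nodes displacements, n_xi multipliers]`.
#' Dirichlet constraints are handled by the caller (see [newton_solve()]),
#' which prescribes values directly in `u` and reduces the system to the
#' free DOFs.
#'
#' @param model An [fe_model].
#' @param u Global displacement vector (length `3 n`) or `n x 3` matrix.
#' @param xi Multiplier vector (length `n_xi`).
#' @param state Load state, e.g. from [apply_schedule()]: list with `alpha`
#'   (temporal activation), `gamma` (per-element activation field values,
#'   length `n_elems`) and `pressures` (named vector of magnitudes per
#'   pressure-load face set).
#' @param want_K Assemble the tangent (default `TRUE`).
#' @return List with `res` (residual), `K` (sparse `dgCMatrix` or `NULL`),
#'   `detC` (per-muscle-element volume ratios) and `inverted` (logical).
#' @export
assemble_system <- function(model, u, xi = NULL, state = list(),
                            want_K = TRUE) {
  stopifnot(inherits(model, "fe_model"))
  s <- model$setup
  mesh <- model$mesh
  n3 <- 3L * s$n_nodes
  ndof <- n3 + s$n_xi
  if (is.null(xi)) xi <- numeric(s$n_xi)
  alpha <- if (is.null(state$alpha)) 1 else state$alpha
  gam <- if (is.null(state$gamma)) numeric(s$n_elems) else state$gamma
  U <- .as_disp_matrix(u, s$n_nodes)
  res <- numeric(ndof)
  detC <- rep(NA_real_, s$n_elems)
  est <- 169L * s$n_elems
  ti <- integer(est); tj <- integer(est); tx <- numeric(est)
  pos <- 0L
  push <- function(ii, jj, vv) {
    k <- length(vv)
    if (pos + k > length(tx)) {
      ti <<- c(ti, integer(k + 1000L))
      tj <<- c(tj, integer(k + 1000L))
      tx <<- c(tx, numeric(k + 1000L))
    }
    ti[pos + 1:k] <<- ii
    tj[pos + 1:k] <<- jj
    tx[pos + 1:k] <<- vv
    pos <<- pos + k
  }
  stab <- model$options$stab
  for (e in seq_len(s$n_elems)) {
    nd <- mesh$tets[e, ]
    Ue <- U[nd, , drop = FALSE]
    N <- if (!is.null(mesh$fiber) && !is.na(mesh$fiber[e, 1]))
      mesh$fiber[e, ] else NULL
    xi_e <- if (s$is_muscle[e]) xi[s$xi_id[e]] else 0
    out <- .elem_core(s$G[[e]], s$V[e], s$mat[[e]], s$is_muscle[e], N,
                      xi_e, alpha * gam[e], stab, Ue, want_K = want_K)
    if (is.null(out))
      return(list(res = res, K = NULL, detC = detC, inverted = TRUE,
                  bad_elem = e))
    dofs <- as.vector(t(cbind(3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L,
                              3L * nd)))
    res[dofs] <- res[dofs] + out$f
    if (s$is_muscle[e]) {
      xd <- n3 + s$xi_id[e]
      res[xd] <- res[xd] + out$r_xi
      detC[e] <- out$detC
    }
    if (want_K) {
      push(rep(dofs, 12L), rep(dofs, each = 12L), as.vector(out$K))
      if (s$is_muscle[e]) {
        xd <- n3 + s$xi_id[e]
        push(dofs, rep(xd, 12L), out$k_uxi)
        push(rep(xd, 12L), dofs, out$k_uxi)
        push(xd, xd, out$k_xixi)
      }
    }
  }
  # follower pressure loads
  prs <- state$pressures
  for (p in model$pressures) {
    q <- if (!is.null(prs) && !is.null(prs[[p$face_set]]))
      prs[[p$face_set]] else 0
    if (q == 0) next
    fext <- pressure_load_residual(mesh, p$face_set, q,
                                   u = U, follower = model$options$follower)
    res[seq_len(n3)] <- res[seq_len(n3)] - fext
    if (want_K && model$options$follower) {
      tr <- .pressure_tangent_triplets(mesh, p$face_set, q, U)
      push(tr$i, tr$j, tr$x)
    }
  }
  # nodal springs to the reference position
  for (sp in model$springs) {
    dofs <- as.vector(t(cbind(3L * (sp$nodes - 1L) + 1L,
                              3L * (sp$nodes - 1L) + 2L, 3L * sp$nodes)))
    res[dofs] <- res[dofs] + sp$k * as.vector(t(U[sp$nodes, , drop = FALSE]))
    if (want_K) push(dofs, dofs, rep(sp$k, length(dofs)))
  }
  K <- NULL
  if (want_K)
    K <- Matrix::sparseMatrix(i = ti[seq_len(pos)], j = tj[seq_len(pos)],
                              x = tx[seq_len(pos)], dims = c(ndof, ndof))
  list(res = res, K = K, detC = detC, inverted = FALSE)
}

#' Dump an assembled system to plain-text files for inspection
#'
#' Writes the sparse tangent in MatrixMarket format (`tangent.mtx`), the
#' residual (`residual.txt`, one value per line) and a small header
#' (`system.txt` with the DOF layout) into a directory — a
#' debugging aid for examining conditioning or symmetry offline.
#'
#' @param model An [fe_model].
#' @param u,xi,state As for [assemble_system()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
dump_system <- function(model, u, xi = NULL, state = list(),
                        dir = "system_dump") {
  asm <- assemble_system(model, u, xi, state, want_K = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(asm$K, file.path(dir, "tangent.mtx"))
  writeLines(sprintf("%.17g", asm$res), file.path(dir, "residual.txt"))
  s <- model$setup
  writeLines(c(sprintf("n_nodes %d", s$n_nodes),
               sprintf("n_displacement_dofs %d", 3L * s$n_nodes),
               sprintf("n_multipliers %d", s$n_xi),
               sprintf("n_fixed_dofs %d", sum(s$fixed))),
             file.path(dir, "system.txt"))
  invisible(dir)
}
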