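strip_model <- function(mesh, mat = muscle_params(a = 2.5, A = 0.8),
                        stab = 1e-3, ...) {
  mats <- list(muscle = mat, bone = isotropic_params(569.23, 853.85))
  fe_model(mesh, mats[unique(mesh$region)], options = list(stab = stab), ...)
}

test_that("element kinematics are exact for affine and rigid motions", {
  m <- make_strip(4, 2, 2, nx = 2, ny = 1, nz = 1)
  n <- nrow(m$nodes)
  expect_equal(element_kinematics(m, 3, numeric(3 * n))$F, diag(3))
  # affine stretch along x reproduced exactly (linear completeness)
  al <- 1.17
  U <- cbind((al - 1) * m$nodes[, 1], 0, 0)
  k <- element_kinematics(m, 5, U)
  expect_equal(k$F, diag(c(al, 1, 1)), tolerance = 1e-14)
  # rigid rotation leaves C at identity (objectivity)
  Q <- rotation_matrix(c(1, 2, 3), 20)
  U <- m$nodes %*% t(Q) - m$nodes
  k <- element_kinematics(m, 1, U)
  expect_equal(k$C, diag(3), tolerance = 1e-12)
  # inverted elements are flagged
  Ubad <- cbind(-1.5 * m$nodes[, 1], 0, 0)
  expect_error(element_kinematics(m, 1, Ubad), "inverted")
})

test_that("element residual vanishes at reference and on isochoric states", {
  m <- make_strip(4, 2, 2, nx = 2, ny = 1, nz = 1)
  mod <- strip_model(m)
  r0 <- element_residual(mod, 1, numeric(3 * nrow(m$nodes)), xi = 0,
                         gamma = 0)
  expect_equal(r0$f, numeric(12))
  expect_equal(r0$r_xi, 0)
  # isochoric uniaxial: constraint entry is zero, det C = 1
  lam <- 1.15
  U <- cbind((lam - 1) * m$nodes[, 1],
             (1 / sqrt(lam) - 1) * m$nodes[, 2],
             (1 / sqrt(lam) - 1) * m$nodes[, 3])
  r <- element_residual(mod, 4, U, xi = 0.02, gamma = 0)
  # r_xi = V (detC - 1) - stab V xi
  expect_equal(r$r_xi, -mod$options$stab * tet_volumes(m)[4] * 0.02,
               tolerance = 1e-10)
})

test_that("assembled residual is the gradient of the total energy", {
  set.seed(5)
  m <- make_strip(6, 2, 2, nx = 3, ny = 1, nz = 1)
  mod <- strip_model(m, stab = 2e-3)
  s <- mod$setup
  n3 <- 3 * nrow(m$nodes)
  u <- 0.03 * rnorm(n3)
  xi <- 0.02 * rnorm(s$n_xi)
  gam <- rep(0.6, s$n_elems)
  state <- list(alpha = 0.9, gamma = gam)
  total_energy <- function(u, xi) {
    E <- 0
    for (e in seq_len(s$n_elems)) {
      kin <- element_kinematics(m, e, u)
      act <- activation_point(gamma = gam[e], alpha = 0.9)
      E <- E + s$V[e] * (strain_energy(kin, mod$materials$muscle, act) +
                           xi[e] * (det(kin$C) - 1)) -
        mod$options$stab / 2 * s$V[e] * xi[e]^2
    }
    E
  }
  asm <- assemble_system(mod, u, xi, state, want_K = FALSE)
  h <- 1e-6
  probe <- sample(n3, 20)
  for (dof in probe) {
    up <- u; up[dof] <- up[dof] + h
    um <- u; um[dof] <- um[dof] - h
    g <- (total_energy(up, xi) - total_energy(um, xi)) / (2 * h)
    expect_equal(asm$res[dof], g, tolerance = 1e-5 * max(1, abs(g)))
  }
  for (k in sample(s$n_xi, 8)) {
    xp <- xi; xp[k] <- xp[k] + h
    xm <- xi; xm[k] <- xm[k] - h
    g <- (total_energy(u, xp) - total_energy(u, xm)) / (2 * h)
    expect_equal(asm$res[n3 + k], g, tolerance = 1e-5 * max(1, abs(g)))
  }
})

test_that("assembled tangent matches global finite differences", {
  set.seed(6)
  m <- make_strip(4, 2, 2, nx = 2, ny = 1, nz = 1)
  mod <- fe_model(m, list(muscle = muscle_params(a = 2.5, A = 0.8)),
                  pressures = list(list(face_set = "y1", from = 0,
                                        to = 5e-3)),
                  options = list(stab = 1e-3))
  s <- mod$setup
  n3 <- 3 * nrow(m$nodes)
  ndof <- n3 + s$n_xi
  u <- 0.02 * rnorm(n3)
  xi <- 0.01 * rnorm(s$n_xi)
  state <- list(alpha = 1, gamma = rep(0.4, s$n_elems),
                pressures = list(y1 = 3e-3))
  asm <- assemble_system(mod, u, xi, state)
  K <- as.matrix(asm$K)
  h <- 1e-7
  resv <- function(u, xi) assemble_system(mod, u, xi, state,
                                          want_K = FALSE)$res
  cols <- sample(ndof, 25)
  for (c_ in cols) {
    up <- c(u, xi); um <- up
    up[c_] <- up[c_] + h
    um[c_] <- um[c_] - h
    fd <- (resv(up[1:n3], up[-(1:n3)]) - resv(um[1:n3], um[-(1:n3)])) /
      (2 * h)
    expect_lt(max(abs(K[, c_] - fd)), 1e-5 * max(1, max(abs(K[, c_]))))
  }
})

test_that("follower pressure loads integrate exactly", {
  # unit square in two triangles: total force q * area along -normal
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(1, 0, -1), c(1, 1, -1), c(0, 1, -1))
  tets <- rbind(c(1, 2, 3, 5), c(1, 3, 4, 5), c(2, 6, 7, 5), c(3, 5, 7, 6),
                c(3, 4, 5, 8), c(3, 8, 5, 7))
  m <- tet_mesh(nodes, tets, face_sets = list(
    top = rbind(c(1, 2, 3), c(1, 3, 4))))
  q <- 0.02
  f <- pressure_load_residual(m, "top", q)
  ftot <- colSums(matrix(f, ncol = 3, byrow = TRUE))
  expect_equal(ftot, c(0, 0, -q), tolerance = 1e-14)  # normal +z, force -z
  # closed surface: net follower force vanishes for any deformation
  ms <- make_strip(3, 2, 2, nx = 2, ny = 2, nz = 2)
  set.seed(8)
  u <- 0.15 * rnorm(3 * nrow(ms$nodes))
  fsum <- numeric(3)
  for (fs in names(ms$face_sets)) {
    fv <- pressure_load_residual(ms, fs, 0.01, u = u, follower = TRUE)
    fsum <- fsum + colSums(matrix(fv, ncol = 3, byrow = TRUE))
  }
  expect_lt(max(abs(fsum)), 1e-10)
  # follower property: doubling the in-plane size quadruples the load
  u2 <- cbind(ms$nodes[, 1], ms$nodes[, 2], ms$nodes[, 3]) # u = X: size x2
  fv1 <- pressure_load_residual(ms, "z1", 0.01, u = NULL)
  fv2 <- pressure_load_residual(ms, "z1", 0.01, u = as.vector(t(u2)))
  s1 <- colSums(matrix(fv1, ncol = 3, byrow = TRUE))
  s2 <- colSums(matrix(fv2, ncol = 3, byrow = TRUE))
  expect_equal(s2, 4 * s1, tolerance = 1e-12)
  # dead-load mode ignores the deformation
  fv3 <- pressure_load_residual(ms, "z1", 0.01, u = as.vector(t(u2)),
                                follower = FALSE)
  expect_equal(fv3, fv1)
})

test_that("system dumps are readable and structurally symmetric", {
  m <- make_strip(2, 1, 1, nx = 2, ny = 1, nz = 1)
  mod <- strip_model(m)
  d <- withr::local_tempdir()
  dump_system(mod, numeric(3 * nrow(m$nodes)),
              state = list(gamma = rep(0.5, nrow(m$tets))), dir = d)
  K <- Matrix::readMM(file.path(d, "tangent.mtx"))
  r <- as.numeric(readLines(file.path(d, "residual.txt")))
  expect_equal(dim(K), rep(3 * nrow(m$nodes) + mod$setup$n_xi, 2))
  expect_equal(length(r), nrow(K))
  # hyperelastic + mixed blocks: symmetric without follower loads
  expect_lt(max(abs(K - Matrix::t(K))), 1e-10 * max(abs(K)))
})

test_that("distorted patch reproduces homogeneous deformation exactly", {
  m0 <- make_strip(2, 2, 2, nx = 2, ny = 2, nz = 2)
  nodes <- m0$nodes
  interior <- which(apply(nodes, 1, function(p)
    all(p > 1e-9) && all(p < 2 - 1e-9)))
  expect_equal(length(interior), 1L)
  set.seed(3)
  nodes[interior, ] <- nodes[interior, ] + c(0.21, -0.13, 0.17)
  m <- tet_mesh(nodes, m0$tets, region = "bone")
  boundary <- setdiff(seq_len(nrow(nodes)), interior)
  A <- matrix(c(1.03, 0.02, 0, 0.01, 0.98, -0.02, 0, 0.015, 1.02), 3, 3,
              byrow = TRUE)
  ub <- nodes[boundary, ] %*% t(A) - nodes[boundary, ]
  mod <- fe_model(m, list(bone = isotropic_params(569.23, 853.85)),
                  dirichlet = list(list(nodes = boundary, comps = 1:3,
                                        value = ub)))
  h <- newton_solve(mod, solve_config(n_increments = 1, newton_tol = 1e-12,
                                      newton_abs_tol = 1e-9))
  U <- displacement(h)
  expect_equal(U[interior, ],
               drop(nodes[interior, ] %*% t(A)) - nodes[interior, ],
               tolerance = 1e-12)
  # every element carries the imposed homogeneous deformation gradient
  for (e in sample(nrow(m$tets), 10))
    expect_equal(element_kinematics(m, e, U)$F, A, tolerance = 1e-11)
})
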