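test_that("strip tessellation has the expected size and exact volume", {
  m <- make_strip(10, 2, 2, nx = 5, ny = 1, nz = 1)
  expect_equal(nrow(m$tets), 30L)
  expect_equal(nrow(m$nodes), 24L)
  expect_equal(mesh_volume(m), 10 * 2 * 2, tolerance = 1e-12)
  expect_true(all(tet_volumes(m) > 0))
  expect_true(all(m$fiber[, 1] == 1 & m$fiber[, 2] == 0 & m$fiber[, 3] == 0))
  # six face sets tiling the closed box boundary
  expect_setequal(names(m$face_sets),
                  c("x0", "x1", "y0", "y1", "z0", "z1"))
  expect_equal(sum(vapply(m$face_sets, nrow, 1L)), nrow(boundary_faces(m)))
})

test_that("strip mesh is conforming", {
  m <- make_strip(6, 4, 2, nx = 3, ny = 2, nz = 1)
  t <- m$tets
  f <- rbind(t[, c(1, 2, 3)], t[, c(1, 2, 4)], t[, c(1, 3, 4)],
             t[, c(2, 3, 4)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  # every interior face shared by exactly two tets, boundary faces by one
  expect_true(all(table(key) <= 2L))
})

test_that("dome fibres are meridional, tangent, and tendon cap is tagged", {
  d <- make_dome(R = 50, thickness = 5, tendon_fraction = 0.3, n_ref = 2)
  mus <- d$region == "diaphragm"
  expect_true(any(mus) && any(d$region == "central_tendon"))
  th <- d$elem_data$theta
  expect_true(all(th[d$region == "central_tendon"] < asin(0.3)))
  expect_true(all(th[mus] >= asin(0.3)))
  # radial-pattern fibre field: tangent to the sphere and purely meridional
  phi <- d$elem_data$phi
  er <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  eph <- cbind(-sin(phi), cos(phi), 0)
  expect_lt(max(abs(rowSums(d$fiber[mus, ] * er[mus, ]))), 1e-6)
  expect_lt(max(abs(rowSums(d$fiber[mus, ] * eph[mus, ]))), 1e-6)
  # fibres point from the tendon cap toward the rim (caudal component < 0)
  expect_true(all(d$fiber[mus, 3] < 0))
})

test_that("dome volume converges to the analytic shell volume", {
  R <- 50; t <- 5
  for (nr in c(2, 3)) {
    d <- make_dome(R, t, tendon_fraction = 0.3, n_ref = nr)
    th0 <- d$meta$th0
    vol <- 2 * pi / 3 * (R^3 - (R - t)^3) * cos(th0)
    relerr <- abs(mesh_volume(d) - vol) / vol
    if (nr == 3) expect_lt(relerr, 0.02)
  }
  # refinement reduces the error monotonically
  errs <- vapply(c(1, 2, 3), function(nr) {
    d <- make_dome(R, t, tendon_fraction = 0.3, n_ref = nr)
    abs(mesh_volume(d) - 2 * pi / 3 * (R^3 - (R - t)^3) * cos(d$meta$th0))
  }, 1)
  expect_true(all(diff(errs) < 0))
  # ventral shear preserves volume exactly
  ds <- make_dome(R, t, tendon_fraction = 0.3, n_ref = 2,
                  sternal_shear = 0.25)
  d2 <- make_dome(R, t, tendon_fraction = 0.3, n_ref = 2)
  expect_equal(mesh_volume(ds), mesh_volume(d2), tolerance = 1e-10)
  expect_error(make_dome(10, 11, 0.3), "thickness")
})

test_that("rib toy obliquity conventions distinguish external and internal", {
  for (orient in c("external", "internal")) {
    m <- make_two_rib_toy(n_ref = 1, n_ribs = 3, orientation = orient)
    expect_true(all(tet_volumes(m) > 0))
    sheet <- m$region %in% c("intercostal", "parasternal")
    expect_true(any(m$region == "parasternal"))
    expect_true(any(m$region == "bone"))
    # ventral-pointing tangent at each sheet element
    umax <- m$meta$umax
    uc <- m$elem_data$unorm * umax
    dots <- numeric(0)
    for (e in which(sheet)) {
      du <- c(cos(uc[e]), -sin(uc[e]), 0)
      tv <- -sign(uc[e] + 1e-15) * du / sqrt(sum(du^2))
      dots <- c(dots, sum(m$fiber[e, ] * tv))
    }
    if (orient == "external") expect_true(all(dots > 0.1))
    else expect_true(all(dots < -0.1))
    # all sheet fibres run caudally
    expect_true(all(m$fiber[sheet, 3] < 0))
  }
})

test_that("rib toy landmarks and fixation sets are present", {
  m <- make_two_rib_toy(n_ref = 1, n_ribs = 4)
  expect_equal(max(m$elem_data$interspace, na.rm = TRUE), 3L)
  for (r in 1:4) {
    expect_true(length(m$node_sets[[paste0("rib", r, "_right")]]) >= 6)
    expect_true(is.numeric(m$node_sets[[paste0("rib", r, "_ventral")]]))
  }
  expect_true(nrow(m$face_sets$vertebral_left) > 0)
  expect_true(nrow(m$face_sets$vertebral_right) > 0)
  # dorsal ends highest, ventral midline drooped caudally
  zv <- m$nodes[m$node_sets$rib1_ventral, 3]
  zd <- m$nodes[m$node_sets$rib1_dorsal, 3]
  expect_gt(zd, zv)
})

test_that("cap surface normals orient as requested", {
  cap <- make_cap_surface(30, center = c(0, 0, 10), theta_max = 50,
                          n_ref = 2, normal = "outward")
  cents <- (cap$nodes[cap$tris[, 1], ] + cap$nodes[cap$tris[, 2], ] +
              cap$nodes[cap$tris[, 3], ]) / 3
  outward <- cents - matrix(c(0, 0, 10), nrow(cents), 3, byrow = TRUE)
  expect_true(all(rowSums(cap$normals * outward) > 0))
  capi <- make_cap_surface(30, center = c(0, 0, 10), theta_max = 50,
                           n_ref = 2, normal = "inward")
  expect_true(all(rowSums(capi$normals * outward) < 0))
})
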