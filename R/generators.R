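# Synthetic thoracic geometries. All generators are deterministic functions
# of their parameters (no RNG) and produce conforming tetrahedral meshes by
# splitting structured hexahedral grids into six tetrahedra per cell; the
# split is fixed in index space, so shared faces always match, including
# across the periodic seam of revolved grids.

# six-tet decomposition of a hex given its 8 corner ids in the order
# c000, c100, c110, c010, c001, c101, c111, c011
.KUHN <- rbind(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
               c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))

# tets for a structured (ni x nj x nk)-cell grid; nid(i,j,k) maps 0-based
# grid indices to node ids (handles periodic wrap); returns list(tets, cell)
# where cell is the (i,j,k) cell index (0-based) of each tet
.grid_tets <- function(ni, nj, nk, nid) {
  ncell <- ni * nj * nk
  tets <- matrix(0L, 6L * ncell, 4L)
  cell <- matrix(0L, 6L * ncell, 3L)
  row <- 0L
  for (k in 0:(nk - 1L)) for (j in 0:(nj - 1L)) for (i in 0:(ni - 1L)) {
    corners <- c(nid(i, j, k), nid(i + 1L, j, k),
                 nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                 nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
    for (t in 1:6) {
      row <- row + 1L
      tets[row, ] <- corners[.KUHN[t, ]]
      cell[row, ] <- c(i, j, k)
    }
  }
  list(tets = tets, cell = cell)
}

# boundary faces of `mesh` whose three nodes all belong to `ids`
.faces_in_nodeset <- function(bfaces, ids) {
  inset <- rep(FALSE, max(bfaces))
  inset[ids] <- TRUE
  bfaces[inset[bfaces[, 1]] & inset[bfaces[, 2]] & inset[bfaces[, 3]], ,
         drop = FALSE]
}

#' Fibre-aligned rectangular strip
#'
#' Box of size `L x W x H` mm tessellated into six tetrahedra per grid cell,
#' with all fibres along one coordinate axis. The workhorse fixture for
#' material-point and uniaxial verification problems. Face sets `x0`, `x1`,
#' `y0`, `y1`, `z0`, `z1` name the six outward-oriented box faces.
#'
#' @param L,W,H Edge lengths (mm, > 0) along x, y, z.
#' @param nx,ny,nz Cell subdivisions (>= 1).
#' @param fiber_axis `"x"`, `"y"` or `"z"`.
#' @param region Region tag for all elements.
#' @return A [tet_mesh] with `6 nx ny nz` elements.
#' @export
make_strip <- function(L, W, H, nx = 5L, ny = 1L, nz = 1L,
                       fiber_axis = "x", region = "muscle") {
  stopifnot(L > 0, W > 0, H > 0, nx >= 1, ny >= 1, nz >= 1)
  ax <- match(match.arg(fiber_axis, c("x", "y", "z")), c("x", "y", "z"))
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  zs <- seq(0, H, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  g <- .grid_tets(nx, ny, nz, nid)
  fiber <- matrix(0, nrow(g$tets), 3L)
  fiber[, ax] <- 1
  mesh <- tet_mesh(nodes, g$tets, fiber = fiber, region = region)
  bf <- boundary_faces(mesh)
  tol <- 1e-9 * max(L, W, H)
  preds <- list(
    x0 = function(p) abs(p[, 1]) < tol, x1 = function(p) abs(p[, 1] - L) < tol,
    y0 = function(p) abs(p[, 2]) < tol, y1 = function(p) abs(p[, 2] - W) < tol,
    z0 = function(p) abs(p[, 3]) < tol, z1 = function(p) abs(p[, 3] - H) < tol)
  mesh$face_sets <- .classify_faces(mesh$nodes, bf, preds)
  mesh$node_sets <- list(
    x0 = which(abs(nodes[, 1]) < tol), x1 = which(abs(nodes[, 1] - L) < tol),
    y0 = which(abs(nodes[, 2]) < tol), y1 = which(abs(nodes[, 2] - W) < tol),
    z0 = which(abs(nodes[, 3]) < tol), z1 = which(abs(nodes[, 3] - H) < tol))
  mesh
}

#' Hemispherical diaphragm dome with radial fibres and central tendon
#'
#' Spherical shell of outer radius `R` and the given thickness, apex up
#' (+z cranial). Elements whose centroid polar angle is below
#' `asin(tendon_fraction)` are tagged `central_tendon` (passive isotropic
#' tissue); the rest are `diaphragm` with fibres tangent to the meridians,
#' the radial pattern running from the central tendon to the rim. A small
#' polar opening (`hole_deg`) inside the tendon cap avoids degenerate
#' elements at the pole.
#'
#' Two optional asymmetries emulate the anatomy of the costal and crural
#' parts: `rim_extend_deg` continues the dorsal meridians below the equator
#' (longer, more vertical dorsal fibres, as for the crura), and
#' `sternal_shear` applies the volume-preserving shear `y <- y - s * z`,
#' which flattens the anterior profile near the central tendon the way the
#' short, near-horizontal sternal fibres do (and steepens the posterior
#' wall); on contraction this asymmetry pulls the dome ventrally as well as
#' caudally, the clinically observed motion.
#'
#' Face sets: `abdominal` (concave lower surface), `pleural` (convex upper
#' surface), `rim` (attachment ring), `apex_hole`. Node sets: `rim`, `apex`
#' (upper rim of the polar opening).
#'
#' @param R Outer radius (mm).
#' @param thickness Shell thickness (mm, < R).
#' @param tendon_fraction Sine of the tendon cap polar angle, in (0, 1).
#' @param n_ref Refinement level (>= 1): `4 n_ref` meridional cells,
#'   `10 n_ref` azimuthal cells, one cell through the thickness.
#' @param rim_extend_deg Maximum dorsal meridian extension beyond the
#'   equator (degrees, >= 0).
#' @param sternal_shear Dimensionless anterior-flattening shear (see
#'   above); 0 gives a symmetric dome.
#' @param hole_deg Polar angle of the apex opening (degrees).
#' @return A [tet_mesh].
#' @export
make_dome <- function(R, thickness, tendon_fraction = 0.35, n_ref = 2L,
                      rim_extend_deg = 0, sternal_shear = 0, hole_deg = 4) {
  stopifnot(R > 0, thickness > 0, tendon_fraction > 0, tendon_fraction < 1,
            n_ref >= 1, rim_extend_deg >= 0, hole_deg > 0)
  if (thickness >= R) stop("degenerate shell: thickness must be < R")
  th_t <- asin(tendon_fraction)
  th0 <- min(hole_deg * pi / 180, 0.5 * th_t)
  nth <- 4L * n_ref
  nph <- 10L * n_ref
  nr <- 1L
  ext <- rim_extend_deg * pi / 180
  thmax <- function(phi) pi / 2 + ext * (1 - sin(phi)) / 2
  rin <- R - thickness
  # node grid: i = 0..nth (meridional), j = 0..nph-1 (periodic), k = 0..nr
  nid <- function(i, j, k) 1L + i + (nth + 1L) * ((j %% nph) + nph * k)
  npts <- (nth + 1L) * nph * (nr + 1L)
  nodes <- matrix(0, npts, 3L)
  shear <- matrix(c(1, 0, 0, 0, 1, 0, 0, -sternal_shear, 1), 3, 3)
  pos <- function(i, j, k) {
    phi <- 2 * pi * j / nph
    th <- th0 + (thmax(phi) - th0) * i / nth
    r <- rin + thickness * k / nr
    drop(shear %*% (r * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))))
  }
  for (k in 0:nr) for (j in 0:(nph - 1L)) for (i in 0:nth)
    nodes[nid(i, j, k), ] <- pos(i, j, k)
  g <- .grid_tets(nth, nph, nr, nid)
  m <- nrow(g$tets)
  # parameter-space centroids (cell midpoints)
  phic <- 2 * pi * (g$cell[, 2] + 0.5) / nph
  thic <- th0 + (vapply(phic, thmax, 1) - th0) * (g$cell[, 1] + 0.5) / nth
  region <- ifelse(thic < th_t, "central_tendon", "diaphragm")
  fiber <- matrix(NA_real_, m, 3L)
  mus <- region == "diaphragm"
  eth <- cbind(cos(thic) * cos(phic), cos(thic) * sin(phic), -sin(thic))
  eth <- t(shear %*% t(eth))
  fiber[mus, ] <- eth[mus, , drop = FALSE] /
    sqrt(rowSums(eth[mus, , drop = FALSE]^2))
  ed <- data.frame(theta = thic, phi = phic)
  mesh <- tet_mesh(nodes, g$tets, fiber = fiber, region = region,
                   elem_data = ed)
  bf <- boundary_faces(mesh)
  grid_ids <- function(ii, kk) {
    out <- integer(0)
    for (k in kk) for (j in 0:(nph - 1L)) for (i in ii)
      out <- c(out, nid(i, j, k))
    unique(out)
  }
  inner_ids <- grid_ids(0:nth, 0L)
  outer_ids <- grid_ids(0:nth, nr)
  rim_ids <- grid_ids(nth, 0:nr)
  hole_ids <- grid_ids(0L, 0:nr)
  mesh$face_sets <- list(
    abdominal = .faces_in_nodeset(bf, inner_ids),
    pleural = .faces_in_nodeset(bf, outer_ids),
    rim = .faces_in_nodeset(bf, rim_ids),
    apex_hole = .faces_in_nodeset(bf, hole_ids))
  mesh$node_sets <- list(rim = rim_ids, apex = grid_ids(0L, nr))
  mesh$meta <- list(R = R, thickness = thickness, th0 = th0, th_t = th_t,
                    rim_extend = ext, sternal_shear = sternal_shear)
  mesh
}

#' Curved rib cage toy with oblique intercostal sheets
#'
#' A stack of curved elastic "rib" beams (bone material) joined by muscle
#' sheets whose fibres make a configurable oblique angle with the rib
#' tangent. The arc spans `arc_deg` degrees symmetric about the ventral
#' midline (+y), with both dorsal ends representing the vertebral
#' attachments; ribs droop caudally toward the ventral midline so that
#' elevating them rotates the cage laterally (bucket handle) and ventrally
#' (pump handle). The ventral portion of every sheet is tagged
#' `parasternal`, the remainder `intercostal`.
#'
#' Fibre obliquity follows the intercostal convention: the `"external"`
#' orientation runs caudoventrally from each rib to the one below
#' (inspiratory), `"internal"` is the mirrored caudodorsal obliquity
#' (expiratory).
#'
#' @param rib_radius Inner radius of the cage (mm).
#' @param rib_sep Vertical interspace height between ribs (mm).
#' @param arc_deg Total arc of the cage (degrees).
#' @param n_ref Refinement level (>= 1): `12 n_ref` arc cells.
#' @param n_ribs Number of ribs (>= 2); `n_ribs - 1` interspaces.
#' @param obliquity Fibre angle to the vertical in the sheet plane (deg).
#' @param orientation `"external"` or `"internal"` fibre obliquity.
#' @param rib_height Vertical height of each rib beam (mm).
#' @param thickness Radial thickness of ribs and sheets (mm).
#' @param droop Caudal droop of the ventral midline relative to the dorsal
#'   ends (mm).
#' @param parasternal_frac Fraction of the half-arc (from the ventral
#'   midline) tagged `parasternal`.
#' @param sternum_frac Fraction of the half-arc around the ventral midline
#'   occupied by the sternum: interspace elements there become `bone`,
#'   joining the rib ends into a ventral column as the sternum does. Set to
#'   0 to omit it.
#' @param cartilage_frac Fraction of the half-arc (from the ventral
#'   midline) over which the rib beams are costal `cartilage` rather than
#'   bone, decoupling individual rib rotations from the sternum as the
#'   compliant costochondral segments do.
#' @return A [tet_mesh] with per-element `interspace`, `unorm` (signed
#'   arc coordinate, +1 at the left dorsal end), and `dorsalness` in
#'   `elem_data`; landmark and fixation sets in `node_sets`/`face_sets`.
#' @export
make_two_rib_toy <- function(rib_radius = 45, rib_sep = 12, arc_deg = 260,
                             n_ref = 1L, n_ribs = 2L, obliquity = 30,
                             orientation = c("external", "internal"),
                             rib_height = 8, thickness = 6, droop = 14,
                             parasternal_frac = 0.35, sternum_frac = 0.09,
                             cartilage_frac = 0.35) {
  orientation <- match.arg(orientation)
  stopifnot(rib_radius > 0, rib_sep > 0, arc_deg > 0, arc_deg < 360,
            n_ref >= 1, n_ribs >= 2, rib_height > 0, thickness > 0,
            droop >= 0)
  umax <- arc_deg / 2 * pi / 180
  ns <- 12L * n_ref
  ngap <- 2L                     # vertical cells per interspace
  # vertical layer table, cranial (t = 0) to caudal
  layers <- list()
  for (r in seq_len(n_ribs)) {
    layers <- c(layers, list(list(region = "bone", h = rib_height,
                                  ncell = 1L, rib = r, interspace = NA)))
    if (r < n_ribs)
      layers <- c(layers, list(list(region = "sheet", h = rib_sep,
                                    ncell = ngap, rib = NA, interspace = r)))
  }
  tcuts <- c(0, cumsum(unlist(lapply(layers, function(l)
    rep(l$h / l$ncell, l$ncell)))))
  nt <- length(tcuts) - 1L
  layer_of_cell <- unlist(lapply(seq_along(layers), function(ix)
    rep(ix, layers[[ix]]$ncell)))
  droop_fn <- function(u) droop * cos(pi * u / (2 * umax))
  nid <- function(j, t, w) 1L + j + (ns + 1L) * (t + (nt + 1L) * w)
  nodes <- matrix(0, (ns + 1L) * (nt + 1L) * 2L, 3L)
  ztop <- max(tcuts)
  for (w in 0:1) for (t in 0:nt) for (j in 0:ns) {
    u <- -umax + 2 * umax * j / ns
    r <- rib_radius + thickness * w
    nodes[nid(j, t, w), ] <- c(r * sin(u), r * cos(u),
                               ztop - tcuts[t + 1L] - droop_fn(u))
  }
  g <- .grid_tets(ns, nt, 1L, nid)
  m <- nrow(g$tets)
  lay <- layer_of_cell[g$cell[, 2] + 1L]
  reg <- vapply(lay, function(ix) layers[[ix]]$region, "")
  itsp <- vapply(lay, function(ix) {
    v <- layers[[ix]]$interspace; if (is.null(v) || is.na(v)) NA_integer_
    else as.integer(v)
  }, 1L)
  ribno <- vapply(lay, function(ix) {
    v <- layers[[ix]]$rib; if (is.null(v) || is.na(v)) NA_integer_
    else as.integer(v)
  }, 1L)
  uc <- -umax + 2 * umax * (g$cell[, 1] + 0.5) / ns
  unorm <- uc / umax
  dorsalness <- abs(unorm)
  sheet <- reg == "sheet"
  region <- reg
  region[sheet & dorsalness < sternum_frac] <- "bone"     # sternum column
  region[sheet & dorsalness >= sternum_frac &
           dorsalness < parasternal_frac] <- "parasternal"
  region[sheet & dorsalness >= parasternal_frac] <- "intercostal"
  sheet <- sheet & region != "bone"
  # costal cartilage: ventral rib segments outside the sternum column
  region[reg == "bone" & !is.na(ribno) & dorsalness >= sternum_frac &
           dorsalness < cartilage_frac] <- "cartilage"
  # oblique fibres in the sheet plane: caudal unit + ventral/dorsal lean
  fiber <- matrix(NA_real_, m, 3L)
  beta <- obliquity * pi / 180
  sgn <- if (orientation == "external") 1 else -1
  for (e in which(sheet)) {
    u <- uc[e]
    du <- c(cos(u) * rib_radius, -sin(u) * rib_radius,
            droop * pi / (2 * umax) * sin(pi * u / (2 * umax)))
    tv <- -sign(u + 1e-15) * du / sqrt(sum(du^2))   # ventral-pointing tangent
    f <- cos(beta) * c(0, 0, -1) + sgn * sin(beta) * tv
    fiber[e, ] <- f / sqrt(sum(f^2))
  }
  ed <- data.frame(interspace = itsp, rib = ribno, unorm = unorm,
                   dorsalness = dorsalness)
  mesh <- tet_mesh(nodes, g$tets, fiber = fiber, region = region,
                   elem_data = ed)
  bf <- boundary_faces(mesh)
  right_ids <- as.vector(outer(0:(nt), 0:1, function(t, w) nid(0L, t, w)))
  left_ids <- as.vector(outer(0:(nt), 0:1, function(t, w) nid(ns, t, w)))
  mesh$face_sets <- list(
    vertebral_right = .faces_in_nodeset(bf, right_ids),
    vertebral_left = .faces_in_nodeset(bf, left_ids))
  # landmark node sets per rib: half-arc node sets and named single nodes
  tcum <- c(0, cumsum(vapply(layers, function(l) l$h, 1)))
  node_t_idx <- function(z) which.min(abs(tcuts - z)) - 1L
  # vertebral attachment as a hinge: only the cranial edge pair of each rib
  # end is fixed, so each rib can rotate about an oblique horizontal axis
  # through its costovertebral attachment (the joint-like behaviour that
  # permits bucket-/pump-handle rotation); the full end faces remain
  # available as `vertebral_clamp` for fully built-in supports
  hinge <- integer(0)
  for (r in seq_len(n_ribs)) {
    ixlay <- which(vapply(layers, function(l) identical(l$rib, r), TRUE))
    ttop <- node_t_idx(tcum[ixlay])
    hinge <- c(hinge, nid(0L, ttop, 0L), nid(0L, ttop, 1L),
               nid(ns, ttop, 0L), nid(ns, ttop, 1L))
  }
  nsets <- list(vertebral = hinge, vertebral_clamp = c(right_ids, left_ids))
  j_of <- function(u) {
    j <- as.integer(round((u + umax) / (2 * umax) * ns))
    min(max(j, 0L), ns)
  }
  for (r in seq_len(n_ribs)) {
    ixlay <- which(vapply(layers, function(l)
      identical(l$rib, r), TRUE))
    tt <- c(node_t_idx(tcum[ixlay]), node_t_idx(tcum[ixlay + 1L]))
    jr <- 0:(ns %/% 2L)                       # right half (u <= 0)
    ids_r <- unique(as.vector(outer(jr, 0:1, function(j, w)
      nid(j, tt[1], w))))
    ids_r <- unique(c(ids_r, as.vector(outer(jr, 0:1, function(j, w)
      nid(j, tt[2], w)))))
    nsets[[paste0("rib", r, "_right")]] <- ids_r
    nsets[[paste0("rib", r, "_lat_left")]] <- nid(j_of(pi / 2), tt[1], 1L)
    nsets[[paste0("rib", r, "_lat_right")]] <- nid(j_of(-pi / 2), tt[1], 1L)
    nsets[[paste0("rib", r, "_ventral")]] <- nid(j_of(0), tt[1], 1L)
    nsets[[paste0("rib", r, "_dorsal")]] <- nid(0L, tt[1], 1L)
  }
  mesh$node_sets <- nsets
  mesh$meta <- list(umax = umax, n_ribs = n_ribs, orientation = orientation,
                    rib_radius = rib_radius, droop = droop)
  mesh
}

#' Triangulated spherical cap surface
#'
#' UV-triangulated cap of a sphere, used as a rigid contact master. With
#' `normal = "outward"` the right-hand normals point away from the centre;
#' `"inward"` flips them (e.g. a cap above a dome, facing it).
#'
#' @param R Sphere radius (mm).
#' @param center Sphere centre (3-vector, mm).
#' @param theta_max Cap polar half-angle (degrees).
#' @param n_ref Refinement (>= 1).
#' @param normal `"outward"` or `"inward"`.
#' @return A [surface_mesh].
#' @export
make_cap_surface <- function(R, center = c(0, 0, 0), theta_max = 60,
                             n_ref = 2L, normal = c("outward", "inward")) {
  normal <- match.arg(normal)
  stopifnot(R > 0, theta_max > 0, theta_max <= 180, n_ref >= 1)
  nth <- 4L * n_ref
  nph <- 10L * n_ref
  thm <- theta_max * pi / 180
  nodes <- matrix(0, 1L + nth * nph, 3L)
  nodes[1L, ] <- center + c(0, 0, R)
  nid <- function(i, j) 1L + (i - 1L) * nph + (j %% nph) + 1L
  for (i in 1:nth) for (j in 0:(nph - 1L)) {
    th <- thm * i / nth
    ph <- 2 * pi * j / nph
    nodes[nid(i, j), ] <- center +
      R * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  tris <- matrix(0L, nph + 2L * nph * (nth - 1L), 3L)
  row <- 0L
  for (j in 0:(nph - 1L)) {
    row <- row + 1L
    tris[row, ] <- c(1L, nid(1L, j), nid(1L, j + 1L))
  }
  for (i in 1:(nth - 1L)) for (j in 0:(nph - 1L)) {
    a <- nid(i, j); b <- nid(i, j + 1L)
    c_ <- nid(i + 1L, j); d <- nid(i + 1L, j + 1L)
    tris[row + 1L, ] <- c(a, c_, d)
    tris[row + 2L, ] <- c(a, d, b)
    row <- row + 2L
  }
  if (normal == "inward") tris <- tris[, c(1L, 3L, 2L)]
  surface_mesh(nodes, tris)
}
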