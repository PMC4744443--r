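#' Tetrahedral mesh with fibres, regions and boundary face sets
#'
#' The central mesh container: node coordinates (mm), tetrahedral
#' connectivity, a per-element reference fibre direction (unit vector, `NA`
#' rows for non-fibrous regions), a per-element region tag used to assign
#' materials and activation fields, named boundary face sets (oriented
#' outward) for pressure and contact surfaces, and named node sets for
#' boundary conditions and kinematic landmarks.
#'
#' @param nodes Numeric `n x 3` matrix of coordinates (mm).
#' @param tets Integer `m x 4` connectivity (1-based). Negative-volume
#'   elements are reoriented by swapping two local nodes when
#'   `fix_orientation` is `TRUE`, otherwise construction fails.
#' @param fiber `m x 3` matrix of reference fibre directions or `NULL`.
#'   Non-`NA` rows are normalised to unit length.
#' @param region Character vector of length `m` (a single tag is recycled).
#' @param face_sets Named list of integer `f x 3` matrices of boundary
#'   triangles, oriented so the right-hand normal points out of the solid.
#' @param node_sets Named list of integer node-index vectors.
#' @param elem_data Optional data frame of per-element auxiliary quantities
#'   (normalised anatomical coordinates, interspace indices, ...).
#' @param fix_orientation Reorient negative tets instead of failing.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, fiber = NULL, region = "solid",
                     face_sets = list(), node_sets = list(),
                     elem_data = NULL, fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L,
            min(tets) >= 1L, max(tets) <= nrow(nodes))
  m <- nrow(tets)
  v <- .tet_volumes(nodes, tets)
  if (any(v == 0)) stop("degenerate tetrahedra in mesh")
  if (any(v < 0)) {
    if (!fix_orientation) stop("negatively oriented tetrahedra in mesh")
    flip <- v < 0
    tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
    v <- abs(v)
  }
  if (!is.null(fiber)) {
    fiber <- as.matrix(fiber)
    stopifnot(nrow(fiber) == m, ncol(fiber) == 3L)
    ok <- !is.na(fiber[, 1])
    nrm <- sqrt(rowSums(fiber[ok, , drop = FALSE]^2))
    if (any(nrm == 0)) stop("zero-length fibre vector")
    fiber[ok, ] <- fiber[ok, , drop = FALSE] / nrm
  }
  region <- rep_len(as.character(region), m)
  stopifnot(is.list(face_sets), is.list(node_sets))
  face_sets <- lapply(face_sets, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "integer"; f
  })
  structure(list(nodes = nodes, tets = tets, fiber = fiber, region = region,
                 face_sets = face_sets, node_sets = node_sets,
                 elem_data = elem_data, volumes = v),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh: %d nodes, %d tets, regions: %s>\n",
              nrow(x$nodes), nrow(x$tets),
              paste(unique(x$region), collapse = ", ")))
  if (length(x$face_sets))
    cat("  face sets:", paste(names(x$face_sets), collapse = ", "), "\n")
  invisible(x)
}

# signed tet volumes
.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
     b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Element volumes and total mesh volume
#'
#' @param mesh A [tet_mesh].
#' @return `tet_volumes()`: vector of positive element volumes (mm^3);
#'   `mesh_volume()`: their sum.
#' @export
tet_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  mesh$volumes
}

#' @rdname tet_volumes
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

#' Boundary triangles of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron, oriented outward (right-hand
#' normal pointing away from the owning element).
#'
#' @param mesh A [tet_mesh].
#' @return Integer `f x 3` matrix of oriented boundary triangles, with the
#'   owning element index in attribute `"elem"`.
#' @export
boundary_faces <- function(mesh) {
  t <- mesh$tets
  # outward-oriented faces of a positively oriented tet (1,2,3,4)
  f <- rbind(t[, c(1L, 3L, 2L)], t[, c(1L, 2L, 4L)],
             t[, c(2L, 3L, 4L)], t[, c(1L, 4L, 3L)])
  owner <- rep(seq_len(nrow(t)), 4L)
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  keep <- cnt[key] == 1L
  out <- f[keep, , drop = FALSE]
  attr(out, "elem") <- owner[keep]
  out
}

# split boundary faces into named sets by a predicate on face centroids
.classify_faces <- function(nodes, faces, predicates) {
  cents <- (nodes[faces[, 1], , drop = FALSE] +
              nodes[faces[, 2], , drop = FALSE] +
              nodes[faces[, 3], , drop = FALSE]) / 3
  out <- lapply(predicates, function(p) {
    sel <- p(cents)
    faces[sel, , drop = FALSE]
  })
  out[vapply(out, nrow, 1L) > 0L]
}

#' Triangulated surface mesh
#'
#' Lightweight surface container used for contact master surfaces and STL
#' input. Triangles are assumed consistently oriented; the right-hand normal
#' is the outward direction used to sign gap distances.
#'
#' @param nodes Numeric `n x 3` coordinate matrix (mm).
#' @param tris Integer `f x 3` triangle connectivity (1-based).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, tris) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tris <- as.matrix(tris)
  storage.mode(tris) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tris) == 3L,
            min(tris) >= 1L, max(tris) <= nrow(nodes))
  n <- .tri_normals(nodes, tris)
  if (any(n$area <= 1e-12))
    stop("degenerate triangle (area <= 1e-12 mm^2) in surface mesh")
  structure(list(nodes = nodes, tris = tris,
                 normals = n$normal, areas = n$area),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d nodes, %d triangles, area %.4g mm^2>\n",
              nrow(x$nodes), nrow(x$tris), sum(x$areas)))
  invisible(x)
}

.tri_normals <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  e1 <- nodes[tris[, 2], , drop = FALSE] - a
  e2 <- nodes[tris[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  list(normal = cr / (2 * area), area = area)
}

#' Extract a face set as a surface mesh
#'
#' @param mesh A [tet_mesh].
#' @param set Name of a face set.
#' @return A [surface_mesh] over the same node coordinates (compacted).
#' @export
face_set_surface <- function(mesh, set) {
  f <- mesh$face_sets[[set]]
  if (is.null(f)) stop("no face set named '", set, "'")
  ids <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$nodes))
  remap[ids] <- seq_along(ids)
  surface_mesh(mesh$nodes[ids, , drop = FALSE],
               matrix(remap[f], ncol = 3L))
}
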