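# Respiratory kinematic read-outs. Rib rotations are reported as the
# bucket-handle angle theta (rotation about the anteroposterior y axis,
# elevating the rib laterally) and the pump-handle angle omega (rotation
# about the transverse x axis, raising the rib ventrally), extracted from
# the best-fit rigid rotation of rib landmark sets. Angles follow the
# right-hand rule about the +y and +x axes (anticlockwise positive); for a
# rib measured on the right side of the cage, elevation gives positive
# theta and ventral-cranial rotation positive omega.

#' Bucket-handle and pump-handle angles from rib landmarks
#'
#' Fits the least-squares rigid rotation (orthogonal Procrustes/Kabsch)
#' mapping the centred reference landmarks to the centred deformed
#' landmarks, then decomposes it in the fixed order
#' `R = Rz(psi) Ry(theta) Rx(omega)`: `theta` is the component about the
#' anteroposterior (y) axis, `omega` about the transverse (x) axis. The
#' result is invariant to landmark relabelling and to uniform translation.
#'
#' @param ref_landmarks,def_landmarks `k x 3` matrices (`k >= 3`,
#'   non-collinear) of corresponding positions (mm).
#' @param rib_id Optional label attached to the result.
#' @return List with `rib_id`, `theta` (degrees), `omega` (degrees),
#'   `psi` (degrees, about z) and the `rotation` matrix.
#' @export
rib_angles <- function(ref_landmarks, def_landmarks, rib_id = NA) {
  P0 <- as.matrix(ref_landmarks)
  P1 <- as.matrix(def_landmarks)
  stopifnot(ncol(P0) == 3L, identical(dim(P0), dim(P1)), nrow(P0) >= 3L)
  c0 <- colMeans(P0); c1 <- colMeans(P1)
  A <- sweep(P0, 2L, c0)
  B <- sweep(P1, 2L, c1)
  sv <- svd(crossprod(A, B))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("rib_angles: landmarks are (nearly) collinear")
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    V <- sv$v; V[, 3] <- -V[, 3]
    R <- V %*% t(sv$u)
  }
  # R = Rz(psi) Ry(theta) Rx(omega)
  theta <- asin(max(-1, min(1, -R[3, 1])))
  omega <- atan2(R[3, 2], R[3, 3])
  psi <- atan2(R[2, 1], R[1, 1])
  list(rib_id = rib_id, theta = theta * 180 / pi, omega = omega * 180 / pi,
       psi = psi * 180 / pi, rotation = R)
}

#' Rib rotation table from a solved rib cage
#'
#' Applies [rib_angles()] to the stored right-half landmark node set of
#' each requested rib (`rib<k>_right`) at a solution increment.
#'
#' @param history A `solution_history` over a rib cage mesh from
#'   [make_two_rib_toy()].
#' @param ribs Integer rib numbers.
#' @param inc Increment index (default: last).
#' @return Data frame with columns `rib`, `theta`, `omega` (degrees).
#' @export
rib_angle_table <- function(history, ribs,
                            inc = length(history$increments)) {
  mesh <- history$model$mesh
  U <- displacement(history, inc)
  out <- lapply(ribs, function(r) {
    ids <- mesh$node_sets[[paste0("rib", r, "_right")]]
    if (is.null(ids)) stop("mesh has no landmark set for rib ", r)
    a <- rib_angles(mesh$nodes[ids, ], mesh$nodes[ids, ] + U[ids, ],
                    rib_id = r)
    data.frame(rib = r, theta = a$theta, omega = a$omega)
  })
  do.call(rbind, out)
}

#' Chest diameter changes at rib levels
#'
#' Clinical-convention diameters before and after deformation: the
#' transverse diameter is the lateral (x) extent between the left and right
#' lateral landmarks, the anteroposterior diameter the ventral (y) extent
#' between the ventral and dorsal landmarks of each level.
#'
#' @param mesh A [tet_mesh] with `rib<k>_lat_left`, `rib<k>_lat_right`,
#'   `rib<k>_ventral`, `rib<k>_dorsal` node sets (as built by
#'   [make_two_rib_toy()]), or explicit `level_defs`.
#' @param u Displacement (`n x 3` matrix or vector).
#' @param levels Integer rib numbers (used with the named sets above).
#' @param level_defs Optional explicit list of
#'   `list(name=, transverse=c(i, j), ap=c(i, j))` node-pair definitions
#'   overriding `levels`.
#' @return Data frame with reference/deformed diameters and their deltas
#'   (mm).
#' @export
chest_diameters <- function(mesh, u, levels = NULL, level_defs = NULL) {
  U <- .as_disp_matrix(u, nrow(mesh$nodes))
  if (is.null(level_defs)) {
    stopifnot(!is.null(levels))
    level_defs <- lapply(levels, function(r) list(
      name = paste0("rib", r),
      transverse = c(mesh$node_sets[[paste0("rib", r, "_lat_left")]],
                     mesh$node_sets[[paste0("rib", r, "_lat_right")]]),
      ap = c(mesh$node_sets[[paste0("rib", r, "_ventral")]],
             mesh$node_sets[[paste0("rib", r, "_dorsal")]])))
  }
  out <- lapply(level_defs, function(ld) {
    x <- mesh$nodes + U
    tr0 <- abs(mesh$nodes[ld$transverse[1], 1] -
                 mesh$nodes[ld$transverse[2], 1])
    tr1 <- abs(x[ld$transverse[1], 1] - x[ld$transverse[2], 1])
    ap0 <- abs(mesh$nodes[ld$ap[1], 2] - mesh$nodes[ld$ap[2], 2])
    ap1 <- abs(x[ld$ap[1], 2] - x[ld$ap[2], 2])
    data.frame(level = ld$name, transverse_ref = tr0, transverse = tr1,
               d_transverse = tr1 - tr0, ap_ref = ap0, ap = ap1,
               d_ap = ap1 - ap0)
  })
  do.call(rbind, out)
}

#' Diaphragm dome kinematics
#'
#' The dome apex is the set of reference-configuration nodes within `tol`
#' of the maximum z (the top of the dome); `MTDDCD` is its mean caudal
#' (-z) displacement, reported positive for caudal motion. Probe locations
#' yield per-increment displacement magnitudes `D(t)`, normalised against
#' the first probe (the `D/D1` series); a vanishing reference-probe
#' displacement flags the series as undefined.
#'
#' @param history A `solution_history` over a dome mesh.
#' @param probes Named list/vector of probe node indices; the first entry
#'   is the normalising location (L1).
#' @param sternum_node Optional node index whose dorsoventral (y)
#'   displacement provides the `ratio = MTDDCD / |sternum_dv|` read-out.
#' @param tol Apex identification tolerance (mm).
#' @return An object of class `dome_metrics`: list with `mtddcd` (mm),
#'   `apex_disp` (mean apex displacement vector), `D` (increments x probes
#'   displacement magnitudes), `d_over_d1`, `sternum_dv`, `ratio`, and
#'   `flagged` (TRUE when D1 is numerically zero).
#' @export
dome_metrics <- function(history, probes = NULL, sternum_node = NULL,
                         tol = 1e-6) {
  mesh <- history$model$mesh
  zmax <- max(mesh$nodes[, 3])
  apex <- which(mesh$nodes[, 3] > zmax - tol)
  ninc <- length(history$increments)
  Ulast <- displacement(history)
  apex_disp <- colMeans(Ulast[apex, , drop = FALSE])
  mtddcd <- -apex_disp[3]
  D <- NULL
  d_over_d1 <- NULL
  flagged <- FALSE
  if (!is.null(probes)) {
    pid <- unlist(probes)
    D <- t(vapply(seq_len(ninc), function(i) {
      U <- displacement(history, i)
      sqrt(rowSums(U[pid, , drop = FALSE]^2))
    }, numeric(length(pid))))
    colnames(D) <- if (!is.null(names(probes))) names(probes)
      else paste0("L", seq_along(pid))
    ref <- D[, 1]
    if (max(abs(ref)) < 1e-12) {
      flagged <- TRUE
      warning("dome_metrics: reference probe L1 has zero displacement; ",
              "D/D1 undefined")
      d_over_d1 <- D * NA_real_
    } else {
      d_over_d1 <- D / ref
      d_over_d1[ref < 1e-12, ] <- NA_real_
    }
  }
  sternum_dv <- if (!is.null(sternum_node))
    Ulast[sternum_node, 2] else NA_real_
  ratio <- if (!is.na(sternum_dv) && abs(sternum_dv) > 1e-9)
    mtddcd / abs(sternum_dv) else NA_real_
  structure(list(mtddcd = mtddcd, apex_disp = apex_disp, apex_nodes = apex,
                 D = D, d_over_d1 = d_over_d1, sternum_dv = sternum_dv,
                 ratio = ratio, flagged = flagged),
            class = "dome_metrics")
}

#' @export
print.dome_metrics <- function(x, ...) {
  cat(sprintf("<dome_metrics: MTDDCD %.3f mm, apex disp (%.3f, %.3f, %.3f) mm%s>\n",
              x$mtddcd, x$apex_disp[1], x$apex_disp[2], x$apex_disp[3],
              if (x$flagged) ", D/D1 flagged" else ""))
  invisible(x)
}
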