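# Frictionless node-to-surface contact against a rigid triangulated master,
# enforced with Lagrange multipliers under the Karush-Kuhn-Tucker conditions
# g >= 0 (no penetration), eta <= 0 (compressive force only), g * eta = 0
# (force only at closing contact).

#' Contact pair between slave nodes and a rigid master surface
#'
#' @param slave_nodes Integer node indices (or the name of a node set) on
#'   the deformable body.
#' @param master A [surface_mesh]; its triangle normals define the positive
#'   (separation) side of the gap.
#' @param gap_tol Geometric tolerance (mm) for activating a node.
#' @param comp_tol Complementarity tolerance for KKT checks (N mm).
#' @return An object of class `contact_pair`.
#' @export
contact_pair <- function(slave_nodes, master, gap_tol = 1e-8,
                         comp_tol = 1e-8) {
  stopifnot(inherits(master, "surface_mesh"), gap_tol > 0)
  structure(list(slave_nodes = slave_nodes, master = master,
                 gap_tol = gap_tol, comp_tol = comp_tol),
            class = "contact_pair")
}

# closest point on each triangle of a surface to p, vectorised over faces;
# returns the global minimum with its face index and closest point
.closest_on_surface <- function(p, surf) {
  A <- surf$nodes[surf$tris[, 1], , drop = FALSE]
  B <- surf$nodes[surf$tris[, 2], , drop = FALSE]
  C <- surf$nodes[surf$tris[, 3], , drop = FALSE]
  P <- matrix(p, nrow(A), 3, byrow = TRUE)
  e1 <- B - A; e2 <- C - A; w <- P - A
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  w1 <- rowSums(w * e1); w2 <- rowSums(w * e2)
  den <- d11 * d22 - d12^2
  s <- (d22 * w1 - d12 * w2) / den
  t <- (d11 * w2 - d12 * w1) / den
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  # interior projection where valid
  cp <- A + s * e1 + t * e2
  # edge closest points (each edge clamped)
  edge_cp <- function(P0, E) {
    tt <- pmin(pmax(rowSums((P - P0) * E) / rowSums(E * E), 0), 1)
    P0 + tt * E
  }
  cands <- list(cp, edge_cp(A, e1), edge_cp(A, e2), edge_cp(B, C - B))
  d2 <- vapply(cands, function(q) rowSums((P - q)^2), numeric(nrow(A)))
  d2[!inside, 1] <- Inf
  best <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(nrow(A)), best)]
  f <- which.min(dmin)
  q <- cands[[best[f]]][f, ]
  list(face = f, point = q, dist = sqrt(dmin[f]))
}

#' Signed gap from a point to a master surface
#'
#' Closest-point distance to the triangulated master, signed positive on
#' the side of the (right-hand) face normals: `g > 0` means separation,
#' `g < 0` penetration.
#'
#' @param point 3-vector (mm).
#' @param master A [surface_mesh].
#' @return List with `g` (signed distance, mm), `closest_face` (index),
#'   `normal` (outward unit normal of that face) and `point` (closest
#'   point).
#' @export
gap <- function(point, master) {
  stopifnot(inherits(master, "surface_mesh"))
  cl <- .closest_on_surface(as.numeric(point), master)
  nrm <- master$normals[cl$face, ]
  sgn <- sign(sum((as.numeric(point) - cl$point) * nrm))
  if (sgn == 0) sgn <- 1
  list(g = sgn * cl$dist, closest_face = cl$face, normal = nrm,
       point = cl$point)
}

# gaps and normals for a set of current node positions
.contact_gaps <- function(xcur, nodes_idx, master) {
  ns <- length(nodes_idx)
  g <- numeric(ns)
  nrm <- matrix(0, ns, 3)
  for (i in seq_len(ns)) {
    gi <- gap(xcur[nodes_idx[i], ], master)
    g[i] <- gi$g
    nrm[i, ] <- gi$normal
  }
  list(g = g, normal = nrm)
}
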