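# Mesh file I/O: Gmsh MSH v2.2, legacy VTK / VTU export, an internal
# plain-text format with bit-exact round-tripping, and ASCII STL input.
# Node indices are 0-based in VTK files and 1-based in MSH; the internal
# representation is 1-based throughout.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a tetrahedral mesh
#'
#' Supported formats: `"msh"` (Gmsh v2.2 ASCII: nodes, 4-node tetrahedra and
#' 3-node boundary triangles; physical volume groups become region tags,
#' physical surface groups become face sets) and `"internal"` (the package's
#' plain-text format written by [write_mesh()], which round-trips nodes,
#' connectivity, fibres, regions, face/node sets and element data
#' bit-exactly).
#'
#' @param path File path.
#' @param format `"msh"` or `"internal"`; default guesses from the
#'   extension (`.msh` vs anything else).
#' @return A [tet_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "msh", "internal")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.msh$", path, ignore.case = TRUE)) "msh"
      else "internal"
  if (!file.exists(path)) stop("no such mesh file: ", path)
  switch(format, msh = .read_msh(path), internal = .read_rfm(path))
}

#' Write a tetrahedral mesh
#'
#' @param mesh A [tet_mesh].
#' @param path Output path.
#' @param format `"vtu"` (XML VTK, with fibres and region codes as cell
#'   data), `"vtk"` (legacy ASCII), `"msh"` (Gmsh v2.2: regions and face
#'   sets as physical groups; fibres are not representable and are
#'   dropped), or `"internal"`.
#' @param point_data Optional named list of per-node vectors/matrices to
#'   embed (VTK formats only), e.g. a displacement field.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("vtu", "vtk", "msh", "internal"),
                       point_data = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- match.arg(format)
  switch(format,
         vtu = .write_vtu(mesh, path, point_data),
         vtk = .write_vtk(mesh, path, point_data),
         msh = .write_msh(mesh, path),
         internal = .write_rfm(mesh, path))
  invisible(path)
}

# ---- internal format -------------------------------------------------------

.write_rfm <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("respifem-mesh 1")
  wl(paste("nodes", nrow(mesh$nodes)))
  wl(apply(mesh$nodes, 1, function(r) paste(.fmt_num(r), collapse = " ")))
  wl(paste("tets", nrow(mesh$tets)))
  wl(apply(mesh$tets, 1, paste, collapse = " "))
  if (!is.null(mesh$fiber)) {
    wl(paste("fiber", nrow(mesh$fiber)))
    wl(apply(mesh$fiber, 1, function(r)
      paste(ifelse(is.na(r), "NA", .fmt_num(r)), collapse = " ")))
  }
  wl(paste("region", length(mesh$region)))
  wl(mesh$region)
  for (nm in names(mesh$face_sets)) {
    f <- mesh$face_sets[[nm]]
    wl(paste("face_set", nm, nrow(f)))
    if (nrow(f)) wl(apply(f, 1, paste, collapse = " "))
  }
  for (nm in names(mesh$node_sets)) {
    ids <- mesh$node_sets[[nm]]
    wl(paste("node_set", nm, length(ids)))
    if (length(ids)) wl(paste(ids, collapse = " "))
  }
  if (!is.null(mesh$elem_data)) {
    wl(paste("elem_data", ncol(mesh$elem_data)))
    for (cn in names(mesh$elem_data)) {
      v <- mesh$elem_data[[cn]]
      wl(paste("column", cn, if (is.integer(v)) "int" else "num"))
      wl(paste(ifelse(is.na(v), "NA", .fmt_num(as.numeric(v))),
               collapse = " "))
    }
  }
  wl("end")
}

.read_rfm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^respifem-mesh", lines[1]))
    stop("parse error at line 1: not a respifem internal mesh file")
  pos <- 2L
  take <- function(n) {
    out <- lines[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  num_block <- function(n, what) {
    m <- matrix(scan(text = take(n), what = "character", quiet = TRUE),
                nrow = n, byrow = TRUE)
    suppressWarnings(matrix(as.numeric(m), nrow = n,
                            dimnames = NULL))
  }
  nodes <- NULL; tets <- NULL; fiber <- NULL; region <- NULL
  face_sets <- list(); node_sets <- list(); elem_data <- NULL
  while (pos <= length(lines)) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    pos <- pos + 1L
    key <- hdr[1]
    if (key == "end") break
    if (key == "nodes") {
      nodes <- num_block(as.integer(hdr[2]))
    } else if (key == "tets") {
      tets <- num_block(as.integer(hdr[2]))
      storage.mode(tets) <- "integer"
    } else if (key == "fiber") {
      fiber <- num_block(as.integer(hdr[2]))
    } else if (key == "region") {
      region <- take(as.integer(hdr[2]))
    } else if (key == "face_set") {
      n <- as.integer(hdr[3])
      f <- if (n > 0) {
        ff <- num_block(n)
        storage.mode(ff) <- "integer"; ff
      } else matrix(integer(0), 0, 3)
      face_sets[[hdr[2]]] <- f
    } else if (key == "node_set") {
      n <- as.integer(hdr[3])
      node_sets[[hdr[2]]] <- if (n > 0)
        as.integer(strsplit(trimws(take(1)), "\\s+")[[1]]) else integer(0)
    } else if (key == "elem_data") {
      ncols <- as.integer(hdr[2])
      cols <- list()
      for (ci in seq_len(ncols)) {
        ch <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
        pos <- pos + 1L
        v <- strsplit(trimws(take(1)), "\\s+")[[1]]
        v <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
        if (ch[3] == "int") v <- as.integer(v)
        cols[[ch[2]]] <- v
      }
      elem_data <- as.data.frame(cols)
    } else {
      stop("parse error at line ", pos - 1L, ": unknown section '", key, "'")
    }
  }
  tet_mesh(nodes, tets, fiber = fiber, region = region,
           face_sets = face_sets, node_sets = node_sets,
           elem_data = elem_data, fix_orientation = FALSE)
}

# ---- Gmsh MSH v2.2 ---------------------------------------------------------

.read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("parse error: missing $MeshFormat section")
  ver <- strsplit(trimws(fmt[1]), "\\s+")[[1]][1]
  if (!startsWith(ver, "2"))
    stop("unsupported MSH version ", ver, " (need v2.x ASCII)")
  phys <- sec("PhysicalNames")
  phys_names <- character(0)
  if (!is.null(phys)) {
    n <- as.integer(phys[1])
    for (i in seq_len(n)) {
      p <- strsplit(trimws(phys[1L + i]), "\\s+")[[1]]
      phys_names[p[2]] <- gsub('"', "", paste(p[-(1:2)], collapse = " "))
    }
  }
  nl <- sec("Nodes")
  nn <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[2:(1L + nn)], quiet = TRUE),
                 nrow = nn, byrow = TRUE)
  # node ids may be non-contiguous; remap
  remap <- integer(max(ntab[, 1]))
  remap[ntab[, 1]] <- seq_len(nn)
  nodes <- ntab[, 2:4, drop = FALSE]
  el <- sec("Elements")
  ne <- as.integer(el[1])
  tets <- list(); tet_phys <- integer(0)
  tris <- list(); tri_phys <- integer(0)
  for (i in seq_len(ne)) {
    v <- as.integer(strsplit(trimws(el[1L + i]), "\\s+")[[1]])
    type <- v[2]; ntags <- v[3]
    ptag <- if (ntags >= 1) v[4] else 0L
    conn <- v[(4L + ntags):length(v)]
    if (type == 4L) {
      tets[[length(tets) + 1L]] <- remap[conn]
      tet_phys <- c(tet_phys, ptag)
    } else if (type == 2L) {
      tris[[length(tris) + 1L]] <- remap[conn]
      tri_phys <- c(tri_phys, ptag)
    } else if (type %in% c(1L, 15L)) {
      next                      # points and lines carry no mesh content here
    } else {
      stop("unsupported element type ", type, " in MSH element ", v[1],
           " (only 4-node tetrahedra and 3-node triangles are read)")
    }
  }
  if (!length(tets)) stop("MSH file contains no tetrahedra")
  tets <- do.call(rbind, tets)
  gname <- function(id) {
    nm <- phys_names[as.character(id)]
    if (is.na(nm) || is.null(nm)) paste0("phys", id) else nm
  }
  region <- vapply(tet_phys, gname, "")
  face_sets <- list()
  if (length(tris)) {
    tris <- do.call(rbind, tris)
    for (id in unique(tri_phys))
      face_sets[[gname(id)]] <- tris[tri_phys == id, , drop = FALSE]
  }
  tet_mesh(nodes, tets, region = region, face_sets = face_sets)
}

.write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  regions <- unique(mesh$region)
  fsets <- names(mesh$face_sets)
  # physical ids: surfaces first (dim 2), then volumes (dim 3)
  ids <- seq_along(c(fsets, regions))
  names(ids) <- c(fsets, regions)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", as.character(length(ids)))
  for (nm in fsets) wl(sprintf('2 %d "%s"', ids[nm], nm))
  for (nm in regions) wl(sprintf('3 %d "%s"', ids[nm], nm))
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(sprintf("%d %s %s %s", seq_len(nrow(mesh$nodes)),
             .fmt_num(mesh$nodes[, 1]), .fmt_num(mesh$nodes[, 2]),
             .fmt_num(mesh$nodes[, 3])))
  wl("$EndNodes")
  ntri <- sum(vapply(mesh$face_sets, nrow, 1L))
  wl("$Elements", as.character(nrow(mesh$tets) + ntri))
  eid <- 0L
  for (nm in fsets) {
    f <- mesh$face_sets[[nm]]
    for (i in seq_len(nrow(f))) {
      eid <- eid + 1L
      wl(sprintf("%d 2 2 %d %d %d %d %d", eid, ids[nm], ids[nm],
                 f[i, 1], f[i, 2], f[i, 3]))
    }
  }
  for (i in seq_len(nrow(mesh$tets))) {
    eid <- eid + 1L
    id <- ids[mesh$region[i]]
    wl(sprintf("%d 4 2 %d %d %d %d %d %d", eid, id, id,
               mesh$tets[i, 1], mesh$tets[i, 2], mesh$tets[i, 3],
               mesh$tets[i, 4]))
  }
  wl("$EndElements")
}

# ---- VTK export ------------------------------------------------------------

.region_codes <- function(mesh) {
  lv <- sort(unique(mesh$region))
  list(codes = match(mesh$region, lv), levels = lv)
}

.write_vtu <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  rc <- .region_codes(mesh)
  wl('<?xml version="1.0"?>',
     '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
     '  <UnstructuredGrid>',
     sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  wl('      <Points>',
     '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  wl(paste(" ", apply(mesh$nodes, 1, function(r)
    paste(.fmt_num(r), collapse = " "))))
  wl('        </DataArray>', '      </Points>')
  wl('      <Cells>',
     '        <DataArray type="Int32" Name="connectivity" format="ascii">')
  wl(paste(" ", apply(mesh$tets - 1L, 1, paste, collapse = " ")))
  wl('        </DataArray>',
     '        <DataArray type="Int32" Name="offsets" format="ascii">')
  wl(paste(" ", paste(seq_len(m) * 4L, collapse = " ")))
  wl('        </DataArray>',
     '        <DataArray type="UInt8" Name="types" format="ascii">')
  wl(paste(" ", paste(rep(10L, m), collapse = " ")))
  wl('        </DataArray>', '      </Cells>')
  wl('      <CellData>')
  wl(sprintf('        <DataArray type="Int32" Name="region" format="ascii"> <!-- %s -->',
             paste(rc$levels, collapse = " ")))
  wl(paste(" ", paste(rc$codes, collapse = " ")))
  wl('        </DataArray>')
  if (!is.null(mesh$fiber)) {
    fib <- mesh$fiber
    fib[is.na(fib)] <- 0
    wl('        <DataArray type="Float64" Name="fiber" NumberOfComponents="3" format="ascii">')
    wl(paste(" ", apply(fib, 1, function(r)
      paste(.fmt_num(r), collapse = " "))))
    wl('        </DataArray>')
  }
  wl('      </CellData>')
  if (length(point_data)) {
    wl('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
      wl(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                 nm, ncol(v)))
      wl(paste(" ", apply(v, 1, function(r)
        paste(.fmt_num(r), collapse = " "))))
      wl('        </DataArray>')
    }
    wl('      </PointData>')
  }
  wl('    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
}

.write_vtk <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  wl("# vtk DataFile Version 3.0", "respifem mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(apply(mesh$nodes, 1, function(r) paste(.fmt_num(r), collapse = " ")))
  wl(sprintf("CELLS %d %d", m, 5L * m))
  wl(apply(mesh$tets - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")))
  wl(sprintf("CELL_TYPES %d", m))
  wl(paste(rep(10L, m), collapse = " "))
  rc <- .region_codes(mesh)
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(paste(rc$codes, collapse = " "))
  if (!is.null(mesh$fiber)) {
    fib <- mesh$fiber
    fib[is.na(fib)] <- 0
    wl("VECTORS fiber double")
    wl(apply(fib, 1, function(r) paste(.fmt_num(r), collapse = " ")))
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (!is.null(dim(v)) && ncol(v) == 3L) {
        wl(sprintf("VECTORS %s double", nm))
        wl(apply(v, 1, function(r) paste(.fmt_num(r), collapse = " ")))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(paste(.fmt_num(as.numeric(v)), collapse = " "))
      }
    }
  }
}

# ---- STL -------------------------------------------------------------------

#' Read an ASCII STL surface
#'
#' Vertices repeated across facets are merged within `tol` (mm) to build a
#' connected triangulation; facet winding is taken as given.
#'
#' @param path STL file path.
#' @param tol Vertex merge tolerance (mm).
#' @return A [surface_mesh].
#' @export
read_stl <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("no such STL file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1])))
    stop("parse error at line 1: not an ASCII STL file")
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("parse error: STL vertex count not a multiple of 3")
  verts <- matrix(scan(text = gsub("vertex", "", vl), quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  key <- apply(round(verts / tol), 1, paste, collapse = "_")
  ids <- match(key, unique(key))
  nodes <- verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(ids, ncol = 3L, byrow = TRUE)
  surface_mesh(nodes, tris)
}
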