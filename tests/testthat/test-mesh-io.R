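test_that("internal format round-trips a generated mesh bit-exactly", {
  m <- make_two_rib_toy(n_ref = 1, n_ribs = 3)
  p <- withr::local_tempfile(fileext = ".rfm")
  write_mesh(m, p, format = "internal")
  m2 <- read_mesh(p, format = "internal")
  expect_identical(m2$nodes, unname(m$nodes))
  expect_identical(m2$tets, unname(m$tets))
  expect_identical(m2$fiber, unname(m$fiber))
  expect_identical(m2$region, m$region)
  expect_identical(lapply(m2$face_sets, unname), lapply(m$face_sets, unname))
  expect_identical(lapply(m2$node_sets, as.integer),
                   lapply(m$node_sets, as.integer))
  expect_equal(m2$elem_data$unorm, m$elem_data$unorm)
  expect_identical(m2$elem_data$interspace, m$elem_data$interspace)
})

test_that("MSH round-trip preserves geometry, regions and face sets", {
  m <- make_strip(4, 2, 2, nx = 2, ny = 1, nz = 1, region = "muscle")
  p <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, p, format = "msh")
  m2 <- read_mesh(p)                     # auto-detects msh
  expect_equal(m2$nodes, unname(m$nodes))
  expect_identical(m2$tets, unname(m$tets))
  expect_identical(m2$region, m$region)
  expect_setequal(names(m2$face_sets), names(m$face_sets))
  expect_identical(unname(m2$face_sets$x0), unname(m$face_sets$x0))
  expect_equal(mesh_volume(m2), mesh_volume(m))
})

test_that("malformed inputs produce explicit parse errors", {
  p <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "1", "1 0 0 0", "$EndNodes",
               "$Elements", "1", "1 5 2 1 1 1 2 3 4 5 6 7 8",
               "$EndElements"), p)
  expect_error(read_mesh(p), "unsupported element type 5")
  p2 <- withr::local_tempfile(fileext = ".rfm")
  writeLines("not a mesh", p2)
  expect_error(read_mesh(p2, format = "internal"), "line 1")
  expect_error(read_mesh("missing_file.rfm"), "no such mesh file")
})

test_that("VTU export carries fibres and regions as cell data", {
  m <- make_strip(2, 1, 1, nx = 2, ny = 1, nz = 1)
  p <- withr::local_tempfile(fileext = ".vtu")
  u <- matrix(0.5, nrow(m$nodes), 3)
  write_mesh(m, p, format = "vtu", point_data = list(displacement = u))
  txt <- readLines(p)
  expect_true(any(grepl('Name="fiber"', txt)))
  expect_true(any(grepl('Name="region"', txt)))
  expect_true(any(grepl('Name="displacement"', txt)))
  expect_true(any(grepl("<Piece NumberOfPoints=\"12\" NumberOfCells=\"12\">",
                        txt)))
  p3 <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, p3, format = "vtk")
  expect_true(any(grepl("VECTORS fiber double", readLines(p3))))
})

test_that("ASCII STL surfaces are read and welded", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid two",
    "facet normal 0 0 1", "outer loop",
    "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
    "endloop", "endfacet",
    "facet normal 0 0 1", "outer loop",
    "vertex 1 0 0", "vertex 1 1 0", "vertex 0 1 0",
    "endloop", "endfacet",
    "endsolid two"), p)
  s <- read_stl(p)
  expect_equal(nrow(s$nodes), 4L)       # shared vertices welded
  expect_equal(nrow(s$tris), 2L)
  expect_equal(sum(s$areas), 1.0)
  expect_equal(s$normals, matrix(c(0, 0, 0, 0, 1, 1), 2, 3))
})
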