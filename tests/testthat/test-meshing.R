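test_that("empty masks give empty meshes with zero area", {
  m <- binary_mask(array(FALSE, dim = c(5, 5, 5)), c(1, 1, 1))
  mesh <- extract_isosurface(m)
  expect_identical(nrow(mesh$faces), 0L)
  expect_identical(mesh_area(mesh), 0)
})

test_that("isosurface area matches analytic solids", {
  cube <- binary_mask(array(TRUE, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_lt(abs(mesh_area(extract_isosurface(cube)) * 100 / 600 - 1), 0.10)

  spec <- sphere_phantom_spec(r = 10, spacing = 0.3)
  ph <- generate_oral_phantom(spec, 1)
  mesh <- extract_isosurface(threshold_segment(ph$volume, -300))
  expect_lt(abs(mesh_area(mesh) * 100 / 1256.637 - 1), 0.03)
  # closed mask -> watertight mesh
  expect_identical(nrow(oralarea:::boundary_edges(mesh)$edges), 0L)
})

test_that("sphere area error shrinks monotonically with voxel size", {
  errs <- vapply(c(1.0, 0.6, 0.3), function(sp) {
    spec <- sphere_phantom_spec(r = 10, spacing = sp)
    ph <- generate_oral_phantom(spec, 1)
    mesh <- extract_isosurface(threshold_segment(ph$volume, -300))
    abs(mesh_area(mesh) * 100 / 1256.637 - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mesh_area is exact, additive and oracle-consistent", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_equal(mesh_area(tri), 0.005, tolerance = 1e-15)

  cm <- cube_mesh(10)
  sub <- 1:5
  comp <- setdiff(seq_len(nrow(cm$faces)), sub)
  expect_equal(mesh_area(cm), mesh_area(cm, sub) + mesh_area(cm, comp),
               tolerance = 1e-12)
  expect_error(mesh_area(cm, c(1, 99)), "out of range")

  spec <- sphere_phantom_spec(r = 5, spacing = 0.5)
  ph <- generate_oral_phantom(spec, 1)
  mesh <- extract_isosurface(threshold_segment(ph$volume, -300))
  expect_equal(mesh_area(mesh), brute_mesh_area(mesh), tolerance = 1e-12)
})

test_that("mesh area is invariant under rigid motions", {
  cm <- cube_mesh(10)
  R <- random_rotation(5)
  moved <- triangle_mesh(sweep(cm$vertices %*% t(R), 2, c(4, -2, 7), "+"),
                         cm$faces)
  expect_equal(mesh_area(moved), mesh_area(cm), tolerance = 1e-12)
})

test_that("flat filling restores a cube's missing face and gates on size", {
  closed <- cube_mesh(10)
  res <- flat_fill_holes(closed, 1e6)
  expect_identical(nrow(res$report), 0L)
  expect_identical(nrow(res$mesh$faces), nrow(closed$faces))

  open <- cube_mesh(10, drop_top = TRUE)
  expect_equal(mesh_area(open) * 100, 500, tolerance = 1e-9)
  filled <- flat_fill_holes(open, 1e6)
  expect_identical(nrow(filled$report), 1L)
  expect_true(filled$report$filled)
  expect_lt(abs(mesh_area(filled$mesh) * 100 / 600 - 1), 0.01)
  # existing faces never removed
  expect_true(nrow(filled$mesh$faces) > nrow(open$faces))

  gated <- flat_fill_holes(open, 1)
  expect_false(gated$report$filled[1])
  expect_identical(nrow(gated$mesh$faces), nrow(open$faces))
})

test_that("non-manifold boundaries are rejected with the vertex named", {
  # two open triangles sharing one vertex: 4 boundary edges at vertex 1
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  F <- rbind(c(1, 2, 3), c(1, 4, 5))
  expect_error(flat_fill_holes(triangle_mesh(V, F)), "non-manifold")
})

test_that("STL round trips preserve faces and area in both dialects", {
  spec <- sphere_phantom_spec(r = 5, spacing = 0.5)
  ph <- generate_oral_phantom(spec, 1)
  mesh <- extract_isosurface(threshold_segment(ph$volume, -300))

  bin <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, bin)
  back <- read_stl(bin)
  expect_identical(nrow(back$faces), nrow(mesh$faces))
  expect_lt(abs(mesh_area(back) / mesh_area(mesh) - 1), 1e-4)

  asc <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, asc, ascii = TRUE)
  back_a <- read_stl(asc)
  expect_identical(nrow(back_a$faces), nrow(mesh$faces))
  expect_lt(abs(mesh_area(back_a) / mesh_area(back) - 1), 1e-6)
})

test_that("truncated STL files raise a parse error, not a partial mesh", {
  cm <- cube_mesh(10)
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(cm, p)
  raw <- readBin(p, "raw", n = file.info(p)$size)
  writeBin(raw[1:(length(raw) - 30)], p)
  expect_error(read_stl(p), "parse error")
  pa <- withr::local_tempfile(fileext = ".stl")
  write_stl(cm, pa, ascii = TRUE)
  lines <- readLines(pa)
  writeLines(lines[1:(length(lines) - 4)], pa)
  expect_error(read_stl(pa), "parse error")
})
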