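test_that("empty spec yields an all-air volume with zero truth areas", {
  spec <- phantom_spec(grid_shape = c(8, 8, 8))
  ph <- generate_oral_phantom(spec, seed = 1)
  expect_true(all(ph$volume$data == -1000))
  expect_true(all(ph$truth$region_area_cm2 == 0))
  expect_identical(dim(ph$truth$voxel_labels), dim(ph$volume$data))
})

test_that("sphere truth area is analytic and the pipeline recovers it", {
  spec <- sphere_phantom_spec(r = 10, spacing = 0.3)
  ph <- generate_oral_phantom(spec, seed = 1)
  expect_equal(ph$truth$region_area_cm2[["TONGUE"]], 4 * pi * 100 / 100,
               tolerance = 1e-12)
  masks <- segment_pipeline(ph$volume)
  area <- mesh_area(extract_isosurface(masks$soft_mask))
  expect_lt(abs(area / 12.56637 - 1), 0.03)
})

test_that("primitives outside the grid are rejected by name", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20),
                       primitives = list(phantom_primitive(
                         "sphere", c(3, 3, 3), 10, "SOFT_TISSUE",
                         "PALATE")))
  expect_error(generate_oral_phantom(spec, 1), "primitive 1.*sphere")
})

test_that("voxelization volume matches analytic volume within 2%", {
  vox <- 0.3^3
  # generic (grid-incommensurate) sizes: faces landing exactly on voxel
  # centres would bias counts by half a voxel per face
  for (p in list(phantom_primitive("sphere", c(7.5, 7.5, 7.5), 5),
                 phantom_primitive("box", c(7.5, 7.5, 7.5),
                                   c(8.12, 6.7, 9.44)),
                 phantom_primitive("cylinder", c(7.5, 7.5, 7.5),
                                   c(4.3, 8.3)))) {
    spec <- phantom_spec(grid_shape = c(50, 50, 50),
                         primitives = list(p))
    ph <- generate_oral_phantom(spec, 1)
    count <- sum(ph$truth$voxel_materials == 2L)
    expect_lt(abs(count * vox / primitive_volume(p) - 1), 0.02,
              label = paste("volume error for", p$shape))
  }
})

test_that("bubbles form exactly the requested number of enclosed air pockets", {
  spec <- sphere_phantom_spec(r = 10, spacing = 0.5, bubble_count = 25)
  ph <- generate_oral_phantom(spec, seed = 42)
  # brute-force component count of air strictly inside the sphere (the
  # surrounding air shell is not a bubble)
  d <- dim(ph$truth$voxel_materials)
  ctr <- 13 / 0.5 + 1  # sphere centre (13 mm) in voxel indices
  xs <- (seq_len(d[1]) - ctr)^2
  # bubbles sit >= 1 mm inside the surface; 9.8 mm keeps them, drops shell
  inside <- outer(outer(xs, xs, "+"), xs, "+") <= (9.8 / 0.5)^2
  air_inside <- (ph$truth$voxel_materials == 1L) & inside
  expect_identical(brute_components6(air_inside), 25L)
  expect_identical(nrow(ph$truth$bubble_centers_mm), 25L)
})

test_that("phantom generation is seed-deterministic and bubble-monotone", {
  spec <- sphere_phantom_spec(r = 8, spacing = 0.5, bubble_count = 5,
                              noise_sd_hu = 20)
  a <- generate_oral_phantom(spec, seed = 9)
  b <- generate_oral_phantom(spec, seed = 9)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$bubble_centers_mm, b$truth$bubble_centers_mm)
  c10 <- generate_oral_phantom(sphere_phantom_spec(r = 8, spacing = 0.5,
                                                   bubble_count = 10),
                               seed = 9)
  m5 <- binary_mask(generate_oral_phantom(
    sphere_phantom_spec(r = 8, spacing = 0.5, bubble_count = 5),
    seed = 9)$truth$voxel_materials == 2L, rep(0.5, 3))
  m10 <- binary_mask(c10$truth$voxel_materials == 2L, rep(0.5, 3))
  expect_gte(count_enclosed_air(m10), count_enclosed_air(m5))
})

test_that("rater tables realize the requested variance structure", {
  perfect <- generate_rater_table(10, c(1, 0, 0), 2, seed = 3)
  expect_equal(icc(perfect)$estimate, 1.0, tolerance = 1e-12)
  expect_error(generate_rater_table(10, c(1, -0.1, 0.2), 2, 1),
               "non-negative")
  expect_error(generate_rater_table(10, c(0, 0.1, 0.2), 2, 1),
               "subject variance")
  a <- generate_rater_table(15, c(1, 0.25, 0.25), 3, seed = 11)
  b <- generate_rater_table(15, c(1, 0.25, 0.25), 3, seed = 11)
  expect_identical(a$values, b$values)
  # mean estimate over repeated designs near the population ICC(A,2) = 0.8
  ests <- vapply(1:200, function(s)
    icc(generate_rater_table(20, c(1, 0.25, 0.25), 2, seed = s))$estimate,
    numeric(1))
  expect_lt(abs(mean(ests) - 0.8), 0.05)
})

test_that("correlated pairs hit the target correlation", {
  d1 <- generate_correlated_pairs(100, 1, seed = 2)
  expect_equal(cor(d1$x, d1$y), 1, tolerance = 1e-12)
  d0 <- generate_correlated_pairs(10000, 0, seed = 2)
  expect_lt(abs(cor(d0$x, d0$y)), 0.05)
  d6 <- generate_correlated_pairs(10000, 0.6, seed = 2)
  expect_lt(abs(cor(d6$x, d6$y) - 0.6), 0.02)
  expect_error(generate_correlated_pairs(10000, 1.2, 1), "r_target")
  expect_identical(generate_correlated_pairs(50, 0.3, 7),
                   generate_correlated_pairs(50, 0.3, 7))
})

test_that("head landmark generator supports repeat-measurement noise", {
  lm0 <- generate_head_landmarks(1, 0)
  lm1 <- generate_head_landmarks(1, 0)
  expect_identical(lm0$points, lm1$points)
  lm2 <- generate_head_landmarks(1, 0.5)
  expect_false(identical(lm0$points, lm2$points))
  # distances at the adult craniofacial scale
  res <- measure_all(lm0)
  expect_true(all(res$value_cm > 1 & res$value_cm < 30))
})
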