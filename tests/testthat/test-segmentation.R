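test_that("thresholding matches its definition and a brute-force count", {
  v <- hu_volume(array(c(-1000, 40, 1200, -301, -300, 349, 350, 351),
                       dim = c(2, 2, 2)), c(1, 1, 1))
  m <- threshold_segment(v, -300)
  expect_identical(as.vector(m$data)[1:3], c(FALSE, TRUE, TRUE))
  expect_true(m$data[1, 1, 2])   # -300 itself is included
  air <- hu_volume(array(-1000, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_false(any(threshold_segment(air, -300)$data))

  set.seed(101)
  g <- hu_volume(array(sample(-1000:2000, 125, TRUE), dim = c(5, 5, 5)),
                 c(1, 1, 1))
  m350 <- threshold_segment(g, 350)
  expect_identical(sum(m350$data), brute_count_ge(g$data, 350))
})

test_that("thresholding is monotone in the threshold", {
  set.seed(7)
  g <- hu_volume(array(rnorm(8^3, 0, 600), dim = c(8, 8, 8)), c(1, 1, 1))
  prev <- threshold_segment(g, -500)$data
  for (thr in c(-300, 0, 350, 800)) {
    cur <- threshold_segment(g, thr)$data
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("Gaussian smoothing preserves identity, constants and mass", {
  set.seed(11)
  v <- hu_volume(array(rnorm(10^3), dim = c(10, 10, 10)), c(1, 1, 1))
  expect_identical(smooth_volume(v, 0)$data, v$data)
  cst <- hu_volume(array(123.4, dim = c(9, 9, 9)), c(1, 1, 1))
  expect_equal(smooth_volume(cst, 1.7)$data, cst$data, tolerance = 1e-12)
  imp <- array(0, dim = c(15, 15, 15))
  imp[8, 8, 8] <- 1000
  iv <- hu_volume(imp, c(1, 1, 1))
  sm <- smooth_volume(iv, 1)
  expect_lt(max(sm$data), 1000)
  expect_equal(sum(sm$data), 1000, tolerance = 1e-6)
  expect_error(smooth_volume(v, -1), "sigma")
})

test_that("closing equals brute-force dilation-then-erosion", {
  blk <- array(TRUE, dim = c(10, 10, 10))
  blk[5, 5, 5] <- FALSE
  m <- binary_mask(blk, c(1, 1, 1))
  closed <- morphological_close(m, 1)
  expect_identical(sum(closed$data), 1000L)
  expect_identical(closed$data, brute_close(blk, 1))

  set.seed(21)
  for (r in 1:2) {
    rnd <- array(runif(20^3) < 0.45, dim = c(20, 20, 20))
    got <- morphological_close(binary_mask(rnd, c(1, 1, 1)), r)
    expect_identical(got$data, brute_close(rnd, r),
                     label = sprintf("closing radius %d", r))
  }
})

test_that("closing leaves convex solids alone but keeps large cavities", {
  solid <- array(FALSE, dim = c(14, 14, 14))
  solid[4:11, 4:11, 4:11] <- TRUE
  m <- binary_mask(solid, c(1, 1, 1))
  expect_identical(morphological_close(m, 2)$data, solid)

  cav <- array(FALSE, dim = c(20, 20, 20))
  ctr <- c(10.5, 10.5, 10.5)
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    if (sum((c(i, j, k) - ctr)^2) <= 8.5^2) cav[i, j, k] <- TRUE
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    if (sum((c(i, j, k) - ctr)^2) <= 5^2) cav[i, j, k] <- FALSE
  cm <- binary_mask(cav, c(1, 1, 1))
  expect_identical(count_enclosed_air(cm), 1L)
  expect_identical(count_enclosed_air(morphological_close(cm, 2)), 1L)
})

test_that("closing is idempotent and extensive on random masks", {
  set.seed(33)
  for (s in 1:3) {
    rnd <- array(runif(15^3) < 0.4, dim = c(15, 15, 15))
    m <- binary_mask(rnd, c(1, 1, 1))
    c1 <- morphological_close(m, 2)
    expect_true(all(c1$data | !m$data))          # extensive
    c2 <- morphological_close(c1, 2)
    expect_identical(c2$data, c1$data)           # idempotent
  }
})

test_that("the pipeline fills sub-millimetre bubbles and keeps provenance", {
  spec <- sphere_phantom_spec(r = 6, spacing = 0.3, bubble_count = 5)
  ph <- generate_oral_phantom(spec, seed = 4)
  raw <- threshold_segment(ph$volume, -300)
  expect_gt(count_enclosed_air(raw), 0L)
  masks <- segment_pipeline(ph$volume)
  expect_identical(count_enclosed_air(masks$soft_mask), 0L)
  expect_match(paste(masks$soft_mask$provenance, collapse = ";"),
               "smooth.*threshold >= -300.*close", ignore.case = TRUE)
  # no bone material anywhere -> bone mask empty
  expect_false(any(masks$bone_mask$data))
})

test_that("soft-mask voxel count tracks the truth labels on a dome", {
  spec <- phantom_spec(grid_shape = c(90, 90, 60),
                       primitives = list(phantom_primitive(
                         "dome", c(13.5, 13.5, 5), 10, "SOFT_TISSUE",
                         "PALATE")))
  ph <- generate_oral_phantom(spec, 1)
  masks <- segment_pipeline(ph$volume)
  truth_n <- sum(ph$truth$voxel_materials == 2L)
  expect_lt(abs(sum(masks$soft_mask$data) / truth_n - 1), 0.02)
})
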