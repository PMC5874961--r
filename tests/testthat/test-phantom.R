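test_that("water tank geometry follows the requested size and spacing", {
  tank <- make_water_tank(c(10, 10, 10), 1)
  expect_equal(dim(tank), c(10L, 10L, 10L))
  expect_equal(sum(tank$rsp), 1000)

  tank2 <- make_water_tank(c(10, 10, 10), 2)
  expect_equal(dim(tank2), c(5L, 5L, 5L))

  big <- make_water_tank(c(300, 300, 400), 1)
  expect_equal(dim(big), c(300L, 300L, 400L))
  expect_true(all(big$rsp == 1))

  expect_error(make_water_tank(c(-10, 10, 10), 1), "positive")
  expect_error(make_water_tank(c(10, 10, 10), 0), "positive")
})

test_that("default grid coordinates center the axis and start depth at 0", {
  g <- make_water_tank(c(20, 20, 30), 2)
  expect_equal(range(voxel_centers(g, 1)), c(-9, 9))
  expect_equal(voxel_centers(g, 3)[1], 1)
  expect_equal(voxel_centers(g, 3)[15], 29)
})

test_that("benchmark phantom places bone and lung blocks as specified", {
  ph <- make_benchmark_phantom()
  g <- ph$grid
  expect_equal(dim(g), c(300L, 300L, 400L))
  xs <- voxel_centers(g, 1); ys <- voxel_centers(g, 2)
  zs <- voxel_centers(g, 3)
  at <- function(x, y, z)
    g$rsp[which.min(abs(xs - x)), which.min(abs(ys - y)),
          which.min(abs(zs - z))]
  expect_equal(at(-5, 0, 175), 1.46)   # bone side
  expect_equal(at(5, 0, 175), 0.217)   # lung side
  expect_equal(at(0.5, 0.5, 100), 1)   # upstream water
  expect_equal(at(-5, 0, 210), 1)      # behind the blocks
  # interface on the beam axis: bone occupies x in [-10, 0)
  expect_equal(at(-0.5, 0, 175), 1.46)
  expect_equal(at(0.5, 0, 175), 0.217)

  # rsp-weighted volume conservation at 1 mm voxels
  n_block <- 10 * 20 * 50
  expect_equal(sum(g$rsp),
               (300 * 300 * 400 - 2 * n_block) + n_block * (1.46 + 0.217))

  expect_error(make_benchmark_phantom(bone_rsp = 0.9), "bone_rsp")
  expect_error(make_benchmark_phantom(lung_rsp = 1.2), "bone_rsp")
})

test_that("CT calibration maps CT numbers through the piecewise-linear table", {
  tab <- default_calibration_table()
  vol <- array(0, dim = c(3, 3, 3))
  g <- ct_volume_to_rsp(vol, tab)
  expect_true(all(g$rsp == 1))

  vol[] <- -1000
  expect_true(all(ct_volume_to_rsp(vol, tab)$rsp == 0.001))

  # midway between two nodes -> mean of node rsp values
  vol[] <- 500
  expect_true(all(abs(ct_volume_to_rsp(vol, tab)$rsp - (1 + 1.46) / 2) < 1e-12))

  # clamped outside the table span
  vol[] <- 5000
  expect_true(all(ct_volume_to_rsp(vol, tab)$rsp == 2.0))

  expect_error(calibration_table(numeric(), numeric()), "empty")
  expect_error(calibration_table(c(-5, 10), c(1, 1.1)), "water anchor")
  expect_error(calibration_table(c(10, 0), c(1.1, 1)), "increasing")
})

test_that("WET along a segment is an exact chord-length rsp sum", {
  tank <- make_water_tank(c(40, 40, 120), 1)
  # fully inside water
  expect_equal(wet_along_segment(tank, c(0, 0, 5), c(0, 0, 105)), 100)
  # zero length
  expect_equal(wet_along_segment(tank, c(1, 2, 3), c(1, 2, 3)), 0)

  slab <- make_slab_phantom(c(40, 40, 200), 1,
                            list(list(x = c(-20, 20), y = c(-20, 20),
                                      z = c(50, 100), rsp = 1.46)))
  expect_equal(wet_along_segment(slab, c(0, 0, 25), c(0, 0, 125)),
               50 + 50 * 1.46)
})

test_that("WET matches a brute-force boundary-walk oracle on oblique rays", {
  set.seed(42)
  g <- make_water_tank(c(20, 24, 30), c(2, 3, 2.5))
  g$rsp[] <- stats::runif(length(g$rsp), 0.2, 2)
  g <- voxel_grid(g$rsp, g$spacing, g$origin)
  for (i in 1:10) {
    p0 <- stats::runif(3, c(-12, -14, -5), c(12, 14, 35))
    p1 <- stats::runif(3, c(-12, -14, -5), c(12, 14, 35))
    expect_equal(wet_along_segment(g, p0, p1), oracle_wet(g, p0, p1),
                 tolerance = 1e-9)
  }
})

test_that("WET is additive along collinear points and scale-invariant in water", {
  g <- make_water_tank(c(30, 30, 60), c(3, 2, 1.5))
  p0 <- c(-4.3, 2.2, 1.7); p2 <- c(6.1, -5.5, 55.3)
  for (f in c(0.25, 0.5, 0.8)) {
    p1 <- p0 + f * (p2 - p0)
    expect_equal(wet_along_segment(g, p0, p1) + wet_along_segment(g, p1, p2),
                 wet_along_segment(g, p0, p2), tolerance = 1e-9)
  }
  # uniform medium: WET = geometric length x rsp regardless of voxel size
  len <- sqrt(sum((p2 - p0)^2))
  for (sp in c(0.5, 1, 3)) {
    gu <- make_water_tank(c(30, 30, 60), sp)
    gu$rsp[] <- 1.3
    gu <- voxel_grid(gu$rsp, gu$spacing, gu$origin)
    expect_equal(wet_along_segment(gu, p0, p2), 1.3 * len, tolerance = 1e-9)
  }
})

test_that("masks select half-open boxes over voxel centers", {
  g <- make_water_tank(c(20, 20, 20), 1)
  m <- mask_box(g, xlim = c(-5, 5), ylim = c(-5, 5), zlim = c(5, 15))
  expect_equal(sum(m), 10 * 10 * 10)
  expect_equal(attr(m, "label"), "region")
  r <- region_box(g, 10, 10)
  expect_equal(sum(r), 10 * 10 * 10)
})
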