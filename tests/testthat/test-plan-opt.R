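test_that("spot lattice covers the footprint anchored at the minimum corner", {
  g <- make_water_tank(c(101, 101, 60), 1)  # odd count: centers on integers
  curve <- make_bragg_curve(55)
  # footprint spanning exactly 60 mm in x and y
  ptv <- mask_box(g, c(-30, 31), c(-30, 31), c(20, 40))
  spots <- generate_spot_grid(ptv, g, curve, lateral_spacing_mm = 12,
                              layer_spacing_wed_mm = 5, margin_mm = 0,
                              rs_range = c(0, 127))
  xs <- sort(unique(vapply(spots, function(s) s$x_iso, 0.0)))
  expect_equal(xs, seq(-30, 30, by = 12))
  expect_equal(length(xs), 6L)

  expect_error(generate_spot_grid(ptv & FALSE, g, curve), "empty")
  expect_error(generate_spot_grid(ptv, g, curve, lateral_spacing_mm = 0),
               "positive")
})

test_that("layers span the PTV WED extent at the requested separation", {
  g <- make_water_tank(c(60, 60, 60), 1)
  curve <- make_bragg_curve(55)
  # water: WED = z; voxel centers from 20.5 to 40.5 -> extent exactly 20 mm
  ptv <- mask_box(g, c(-10, 10), c(-10, 10), c(20, 41))
  spots <- generate_spot_grid(ptv, g, curve, layer_spacing_wed_mm = 5,
                              rs_range = c(0, 127))
  layers <- sort(unique(vapply(spots, function(s) s$layer_wed, 0.0)))
  expect_equal(layers, 20.5 + c(0, 5, 10, 15, 20))
  # range-shifter selection puts each layer's peak at the layer WED
  for (s in spots[seq(1, length(spots), by = 7)])
    expect_lte(abs((curve_peak_depth(curve) - 1.16 * s$rs_thickness) -
                     s$layer_wed), 1.16 / 2 + 1e-9)
})

test_that("kernel matrix assembly restricts kernels to the union mask", {
  g <- make_water_tank(c(10, 10, 10), 2)
  mk <- function(val) {
    d <- array(0, dim = dim(g))
    d[3, 3, 3] <- val
    structure(c(unclass(dose_grid(d, g$spacing, g$origin)),
                list(spot = spot(0, 0), n_protons = 1L, seed = 1L)),
              class = c("dose_kernel", "dose_grid"))
  }
  mask <- array(FALSE, dim = dim(g)); mask[3, 3, 3] <- TRUE
  km <- assemble_kernel_matrix(list(mk(2.5)), mask)
  expect_equal(dim(km$A), c(1L, 1L))
  expect_equal(km$A[1, 1], 2.5)

  km0 <- assemble_kernel_matrix(list(mk(0), mk(0)), mask)
  expect_true(all(km0$A == 0))

  # superposition: matrix x ones = sum of kernels on the mask
  mask2 <- array(FALSE, dim = dim(g)); mask2[2:4, 3, 3] <- TRUE
  km2 <- assemble_kernel_matrix(list(mk(1), mk(3)), mask2)
  expect_equal(as.numeric(km2$A %*% c(1, 1)),
               (mk(1)$dose + mk(3)$dose)[which(mask2)])
})

test_that("optimizer solves closed-form and identity systems exactly", {
  # single spot with uniform unit dose d in the PTV -> w = P / d
  A <- matrix(0.25, nrow = 6, ncol = 1)
  w <- optimize_weights(A, ptv_rows = 1:6, prescription = 2)
  expect_equal(as.numeric(w), 8, tolerance = 1e-9)

  # identity kernel matrix -> every weight equals the prescription
  I5 <- diag(5)
  w5 <- optimize_weights(I5, ptv_rows = 1:5, prescription = 3)
  expect_equal(as.numeric(w5), rep(3, 5), tolerance = 1e-6)

  expect_error(optimize_weights(matrix(0, 3, 2), 1:3, 1), "degenerate")
  expect_error(optimize_weights(matrix(1, 3, 2), 1:3, -1), "positive")
})

test_that("optimizer reaches the exhaustive active-set NNLS optimum", {
  for (seed in 1:4) {
    set.seed(seed)
    A <- matrix(stats::runif(5 * 3), 5, 3)
    # make some columns conflict so the NNLS boundary is active
    A[, 3] <- A[, 1] * 0.9 + stats::runif(5, 0, 0.05)
    P <- 1
    w <- optimize_weights(A, ptv_rows = 1:5, prescription = P,
                          tol = 1e-12, max_iter = 20000)
    oracle <- oracle_nnls(A, rep(P, 5))
    expect_true(all(w >= 0))
    expect_equal(attr(w, "objective"), oracle$objective,
                 tolerance = 1e-6)
    expect_equal(as.numeric(w), oracle$w, tolerance = 1e-4)
  }
})

test_that("optimizer objective is non-increasing and respects OAR penalties", {
  set.seed(9)
  A <- matrix(stats::runif(40 * 8), 40, 8)
  w <- optimize_weights(A, ptv_rows = 1:30, prescription = 1)
  expect_true(all(diff(attr(w, "history")) <= 0))
  expect_true(all(w >= 0))

  # a strong OAR overdose penalty lowers the OAR dose
  oar <- list(list(rows = 31:40, cap = 0.5, lambda = 50))
  w2 <- optimize_weights(A, ptv_rows = 1:30, prescription = 1,
                         oar_terms = oar)
  d_oar <- function(w) mean(A[31:40, ] %*% as.numeric(w))
  expect_lt(d_oar(w2), d_oar(w))
})

test_that("total dose is a linear superposition of kernels", {
  g <- make_water_tank(c(10, 10, 10), 2)
  mk <- function(seed) {
    set.seed(seed)
    d <- array(stats::runif(prod(dim(g))), dim = dim(g))
    structure(c(unclass(dose_grid(d, g$spacing, g$origin)),
                list(spot = spot(0, 0), n_protons = 1L, seed = seed)),
              class = c("dose_kernel", "dose_grid"))
  }
  ks <- list(mk(1), mk(2), mk(3))
  expect_true(all(total_dose(ks, c(0, 0, 0))$dose == 0))
  td <- total_dose(ks, c(1, 2, 0.5))
  expect_equal(td$dose, ks[[1]]$dose + 2 * ks[[2]]$dose + 0.5 * ks[[3]]$dose)
  # doubling the weights doubles the dose
  expect_equal(total_dose(ks, 2 * c(1, 2, 0.5))$dose, 2 * td$dose)
  # unit vector picks out one kernel
  expect_equal(total_dose(ks, c(0, 1, 0))$dose, ks[[2]]$dose)
  expect_error(total_dose(ks, c(1, 2)), "lengths differ")
})

test_that("plans round-trip through JSON", {
  spots <- list(spot(0, 0, 206, 10, 100), spot(12, -12, 206, 20, 90))
  plan <- list(field_id = "f1", prescription = 2, spots = spots,
               weights = c(1.5, 2.5))
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  p2 <- read_plan(f)
  expect_equal(p2$prescription, 2)
  expect_equal(p2$weights, c(1.5, 2.5))
  expect_equal(p2$spots[[2]]$x_iso, 12)
  expect_equal(p2$spots[[2]]$rs_thickness, 20L)
})
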