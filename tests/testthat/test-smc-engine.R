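# shared small fixtures for the engine tests
eng_fix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- default_source_table()
      cache <<- list(
        curve = make_bragg_curve(150),
        st = st,
        src = lookup_source(st, 2),
        spot = spot(0, 0, energy = 206, rs_thickness = 2),
        tank = make_water_tank(c(100, 100, 170), 1))
    }
    cache
  }
})

test_that("Highland per-step kick matches direct evaluation and telescopes", {
  sm <- scattering_model()
  # direct one-line evaluation of the Highland expression
  expected <- (14.1 / 300) * sqrt(10 / 360.8) * (1 + log10(10 / 360.8) / 9)
  expect_equal(highland_sigma(sm, 300, 0, 10), expected, tolerance = 1e-12)
  expect_equal(highland_sigma(sm, 300, 0, 10) * 1e3, 6.47, tolerance = 0.01)
  expect_equal(highland_sigma(sm, 300, 5, 0), 0)
  expect_error(highland_sigma(sm, -10, 0, 1), "positive")

  # kicks add in quadrature to the cumulative value over any partition
  W <- 180
  for (nstep in c(3, 10, 37)) {
    edges <- seq(0, W, length.out = nstep + 1)
    s2 <- sum(highland_sigma(sm, 250, edges[-length(edges)], diff(edges))^2)
    expect_equal(sqrt(s2), highland_theta0(sm, 250, W), tolerance = 1e-12)
  }

  # log-correction floor keeps thin-layer kicks real
  expect_true(is.finite(highland_sigma(sm, 300, 0, 1e-12)))
  smoff <- scattering_model(log_correction = FALSE)
  expect_equal(highland_theta0(smoff, 300, 10),
               (14.1 / 300) * sqrt(10 / 360.8), tolerance = 1e-12)
})

test_that("transport of an empty ensemble returns an all-zero grid", {
  fx <- eng_fix()
  ens <- sample_spot_protons(fx$src, fx$spot, 0, seed = 1)
  rm_ <- default_range_model(fx$spot, fx$curve)
  dg <- transport(ens, fx$tank, fx$curve, rm_)
  expect_true(all(dg$dose == 0))
})

test_that("dose is conserved in a containing water tank", {
  fx <- eng_fix()
  n <- 5e3
  k <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, n, seed = 2)
  expected <- dose_between(fx$curve, rs_wet(2), fx$curve$nominal_range)
  expect_equal(sum(k$dose), expected, tolerance = 5e-3)
})

test_that("kernels are deterministic and normalized per proton", {
  fx <- eng_fix()
  k1 <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, 2000, seed = 11)
  k2 <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, 2000, seed = 11)
  expect_identical(k1$dose, k2$dose)
  k3 <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, 2000, seed = 12)
  expect_false(identical(k1$dose, k3$dose))

  # kernel x n equals the raw transport sum
  ens <- sample_spot_protons(fx$src, fx$spot, 2000, seed = 11)
  raw <- transport(ens, fx$tank, fx$curve,
                   default_range_model(fx$spot, fx$curve),
                   rs_wet_mm = rs_wet(2))
  expect_equal(k1$dose * 2000, raw$dose, tolerance = 1e-12)
})

test_that("water-tank depth dose reproduces the input curve shape", {
  fx <- eng_fix()
  k <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, 2e4, seed = 4)
  lidd <- laterally_integrated_depth_dose(k)
  ref <- dose_between(fx$curve, rs_wet(2) + pmax(lidd$z - 0.5, 0),
                      rs_wet(2) + lidd$z + 0.5)
  resid <- lidd$dose / max(lidd$dose) - ref / max(ref)
  expect_lt(sqrt(mean(resid^2)), 0.02)
})

test_that("scaling all stopping powers by k shortens the range by 1/k", {
  fx <- eng_fix()
  falloff80 <- function(scale) {
    g <- fx$tank
    g$rsp[] <- scale
    g <- voxel_grid(g$rsp, g$spacing, g$origin)
    k <- compute_kernel(fx$spot, g, fx$curve, fx$st, 5e3, seed = 6)
    lidd <- laterally_integrated_depth_dose(k)
    pk <- which.max(lidd$dose)
    distal <- lidd$dose[pk:length(lidd$dose)]
    zd <- lidd$z[pk:length(lidd$z)]
    i <- which(distal < 0.8 * max(lidd$dose))[1]
    # linear interpolation of the 80% crossing
    z1 <- zd[i - 1]; z2 <- zd[i]
    d1 <- distal[i - 1]; d2 <- distal[i]
    z1 + (z2 - z1) * (d1 - 0.8 * max(lidd$dose)) / (d1 - d2)
  }
  r1 <- falloff80(1)
  r2 <- falloff80(1.2)
  expect_equal(r1 / r2, 1.2, tolerance = 0.02)
})

test_that("lateral spread in water follows the Fermi-Eyges closed form", {
  fx <- eng_fix()
  k <- compute_kernel(fx$spot, fx$tank, fx$curve, fx$st, 5e4, seed = 8)
  rm_ <- default_range_model(fx$spot, fx$curve)
  fe <- fermi_eyges_sigma(fx$tank, 0, 0, fx$curve, fx$src, rm_,
                          rs_wet_mm = rs_wet(2))
  xs <- voxel_centers(fx$tank, 1)
  R <- fx$curve$nominal_range
  zs <- voxel_centers(fx$tank, 3)
  for (iz in which(zs %in% c(40.5, 80.5, 110.5))) {
    expect_equal(lateral_sd(k$dose, xs, iz), fe$sigma_x[iz], tolerance = 0.05)
  }
})

test_that("bone/lung interface makes the Monte Carlo kernel asymmetric", {
  # miniature version of the heterogeneity benchmark
  slabs <- list(
    list(x = c(-10, 0), y = c(-10, 10), z = c(60, 110), rsp = 1.46),
    list(x = c(0, 10), y = c(-10, 10), z = c(60, 110), rsp = 0.217))
  g <- make_slab_phantom(c(120, 120, 200), 1, slabs)
  st <- default_source_table()
  curve <- make_bragg_curve(167.5)
  sp <- spot(0, 0, rs_thickness = 2)
  k <- compute_kernel(sp, g, curve, st, 3e4, seed = 13, rs_in_curve = TRUE)
  # bone-path peak is 23 mm shallower than the water peak
  lidd <- laterally_integrated_depth_dose(k)
  pks <- find_peaks(lidd$z, lidd$dose)
  expect_gte(nrow(pks), 2)
  expect_lte(abs(min(pks$z) - 144.5), 2)

  # lateral profile at the bone-path peak depth: skewed toward the lung side
  xs <- voxel_centers(g, 1)
  iz <- which.min(abs(voxel_centers(g, 3) - 144.5))
  prof <- rowSums(k$dose[, , iz])
  m <- sum(prof * xs) / sum(prof)
  s <- sqrt(sum(prof * (xs - m)^2) / sum(prof))
  skew <- sum(prof * (xs - m)^3) / sum(prof) / s^3
  expect_gt(abs(skew), 0.1)

  # the analytical kernel at the same depth is exactly mirror-symmetric
  kp <- pba_kernel(sp, g, curve, st, rs_in_curve = TRUE)
  pp <- rowSums(kp$dose[, , iz])
  expect_equal(pp, rev(pp), tolerance = 1e-12)
})

test_that("batch statistical error estimates known per-batch noise", {
  # deterministic identical batches -> 0 %
  m0 <- matrix(rep(c(1, 2, 3), 4), nrow = 3)
  expect_equal(batch_statistical_error(m0), 0)

  # synthetic voxel doses with known per-batch sd
  set.seed(21)
  nb <- 30
  mu <- stats::runif(200, 0.5, 1)
  sdv <- 0.05
  m <- matrix(stats::rnorm(200 * nb, mean = mu, sd = sdv), nrow = 200)
  est <- batch_statistical_error(m)
  expected <- 100 * sdv / (max(rowMeans(m)) * sqrt(nb))
  expect_equal(est, expected, tolerance = 0.2)
  expect_error(batch_statistical_error(m[, 1, drop = FALSE]), "batches")
})

test_that("Monte Carlo statistical error scales as 1/sqrt(n)", {
  fx <- eng_fix()
  mask <- mask_box(fx$tank, c(-10, 10), c(-10, 10), c(130, 150))
  e1 <- estimate_statistical_error(fx$spot, fx$tank, fx$curve, fx$st, mask,
                                   n = 4000, batches = 4, seed = 31)
  e2 <- estimate_statistical_error(fx$spot, fx$tank, fx$curve, fx$st, mask,
                                   n = 16000, batches = 4, seed = 31)
  expect_gt(e1, 0)
  expect_equal(e1 / e2, 2, tolerance = 0.3)
  expect_error(estimate_statistical_error(fx$spot, fx$tank, fx$curve, fx$st,
                                          mask & FALSE, n = 100, batches = 2),
               "empty")
})
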