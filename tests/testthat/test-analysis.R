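test_that("laterally integrated depth dose sums the transverse planes", {
  d <- array(0, dim = c(4, 4, 6))
  d[2, 3, 4] <- 7
  dg <- dose_grid(d, c(1, 1, 1), c(0, 0, 0.5))
  lidd <- laterally_integrated_depth_dose(dg)
  expect_equal(sum(lidd$dose > 0), 1L)
  expect_equal(lidd$dose[4], 7)
  # conservation for a random grid
  d2 <- random_dose_array(c(5, 4, 3), seed = 2)
  dg2 <- dose_grid(d2, c(1, 1, 1), c(0, 0, 0.5))
  expect_equal(sum(laterally_integrated_depth_dose(dg2)$dose), sum(d2))
})

test_that("rms relative difference matches its definition exactly", {
  a <- random_dose_array(c(4, 4, 4), seed = 3)
  b <- random_dose_array(c(4, 4, 4), seed = 4)
  mask <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(rms_relative_difference(a, a, mask), 0)
  # constant offset: 100 * c / max(b)
  expect_equal(rms_relative_difference(b + 0.1, b, mask),
               100 * 0.1 / max(b), tolerance = 1e-12)
  # brute-force elementwise oracle
  expect_equal(rms_relative_difference(a, b, mask),
               100 * sqrt(mean((a - b)^2)) / max(b), tolerance = 1e-12)
  # normalizer is the second argument: not symmetric
  expect_false(isTRUE(all.equal(rms_relative_difference(a, b, mask),
                                rms_relative_difference(b, a, mask))))
  expect_error(rms_relative_difference(a, b, mask & FALSE), "empty")
  expect_error(rms_relative_difference(a, a * 0, mask), "zero")
})

test_that("DVH and D-at-volume follow order statistics", {
  mask <- array(TRUE, dim = c(10, 10, 10))
  uni <- array(1, dim = c(10, 10, 10))
  dv <- dvh(uni, mask, prescription = 1)
  expect_equal(dv$volume_percent[1], 100)
  expect_true(all(diff(dv$volume_percent) <= 0))
  expect_equal(d_at_volume(dv, 95), 100, tolerance = 0.11)

  # uniformly distributed doses on [0, 100]%: D95 is the 5th percentile
  vals <- seq(0, 1, length.out = 1000)
  du <- array(vals, dim = c(10, 10, 10))
  dvu <- dvh(du, mask, prescription = 1)
  expect_equal(d_at_volume(dvu, 95), 5, tolerance = 0.3)
  expect_equal(d_at_volume(dvu, 5), 95, tolerance = 0.3)

  # single-voxel structure: a step DVH with D95 at the voxel dose
  m1 <- array(FALSE, dim = c(10, 10, 10)); m1[5, 5, 5] <- TRUE
  du2 <- du; du2[5, 5, 5] <- 0.42
  expect_equal(d_at_volume(dvh(du2, m1, 1), 95), 42, tolerance = 0.11)

  # permutation invariance within the mask
  set.seed(11)
  dp <- du
  dp[mask] <- sample(du[mask])
  dvp <- dvh(dp, mask, prescription = 1)
  expect_equal(dvp$volume_percent, dvu$volume_percent)

  expect_error(dvh(du, mask & FALSE, 1), "empty")
  expect_error(d_at_volume(dvu, 0), "0, 100")
})

test_that("gamma analysis matches the brute-force oracle voxel by voxel", {
  dims <- c(6, 6, 6)
  sp <- c(2, 2, 2)
  for (seed in c(5, 6)) {
    ref_arr <- random_dose_array(dims, seed = seed) + 0.2
    ev_arr <- ref_arr * (1 + 0.04 * random_dose_array(dims, seed = seed + 10))
    ref <- dose_grid(ref_arr, sp, c(0, 0, 1))
    ev <- dose_grid(ev_arr, sp, c(0, 0, 1))
    res <- gamma_index(ref, ev, dta_mm = 3, dd_percent = 3,
                       dose_cutoff_percent = 10)
    g_or <- oracle_gamma(ref_arr, ev_arr, sp, c(0, 0, 1), 3,
                         0.03 * max(ref_arr), 0.1 * max(ref_arr),
                         search_mm = 6, sub_mm = 1)
    expect_equal(is.na(res$gamma), is.na(g_or))
    # exact agreement of pass/fail per analyzed voxel
    expect_identical(res$gamma <= 1, g_or <= 1)
    expect_equal(res$gamma, g_or, tolerance = 1e-9)
  }
})

test_that("gamma pass rate behaves like a dose-comparison metric", {
  z <- seq(1, 40, by = 2)
  wedge <- array(rep(z, each = 25), dim = c(5, 5, 20))  # steep z-gradient
  ref <- dose_grid(wedge, c(2, 2, 2), c(0, 0, 1))
  expect_equal(gamma_index(ref, ref, 3, 3)$pass_rate, 100)
  # a global 2% scaling passes a 3% criterion everywhere
  ev2 <- dose_grid(wedge * 1.02, c(2, 2, 2), c(0, 0, 1))
  expect_equal(gamma_index(ref, ev2, 3, 3)$pass_rate, 100)
  # shifting the wedge by 2 x dta along the gradient fails somewhere
  shifted <- array(0, dim = dim(wedge))
  shifted[, , 4:20] <- wedge[, , 1:17]
  ev3 <- dose_grid(shifted, c(2, 2, 2), c(0, 0, 1))
  expect_lt(gamma_index(ref, ev3, 3, 3)$pass_rate, 100)

  # monotone non-decreasing in both criteria
  rates <- outer(c(1, 2, 3), c(1, 2, 3), Vectorize(function(dta, dd)
    gamma_index(ref, ev3, dta, dd)$pass_rate))
  expect_true(all(diff(rates) >= 0))          # rows: increasing dta
  expect_true(all(apply(rates, 1, diff) >= 0))  # cols: increasing dd

  expect_error(gamma_index(ref, ev3, -1, 3), "positive")
  zero <- dose_grid(wedge * 0 + 1e-9, c(2, 2, 2), c(0, 0, 1))
  expect_error(gamma_index(zero, zero, 3, 3, dose_cutoff_percent = 200),
               "cutoff")
})

test_that("isodose reports are written and vanish for identical inputs", {
  d <- random_dose_array(c(8, 8, 10), seed = 30)
  dg <- dose_grid(d, c(2, 2, 2), c(0, 0, 1))
  pre <- file.path(tempdir(), "iso_test")
  files <- export_isodose_report(dg, dg, path_prefix = pre)
  expect_true(all(file.exists(files)))
  diff_csv <- utils::read.csv(files["diff"])
  expect_true(all(abs(as.matrix(diff_csv)) == 0))
  # round-trip of the difference slice
  dg2 <- dose_grid(d * 1.1, c(2, 2, 2), c(0, 0, 1))
  files2 <- export_isodose_report(dg, dg2, plane = 4, path_prefix = pre)
  got <- as.matrix(utils::read.csv(files2["diff"]))
  dimnames(got) <- NULL
  expect_equal(got, d[, 4, ] - 1.1 * d[, 4, ], tolerance = 1e-12)
  unlink(files2)
})
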