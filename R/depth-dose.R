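#' Pristine depth-dose curve in water
#'
#' The scoring lookup of the transport engines: laterally integrated dose per
#' proton per mm of water, tabulated against water-equivalent depth. The
#' curve implicitly carries everything folded into a measured integral depth
#' dose — range straggling, nuclear attenuation of the primary fluence,
#' secondary-particle buildup — which is why the Monte Carlo engine itself
#' never samples energy straggling or nuclear interactions.
#'
#' `nominal_range` is the largest tabulated depth at which the dose still
#' exceeds 1e-6 of the peak; transported protons terminate there.
#'
#' @param depth strictly increasing depths in mm starting at 0.
#' @param dose non-negative dose values (arbitrary units / proton / mm).
#' @return a `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depth, dose) {
  depth <- as.numeric(depth); dose <- as.numeric(dose)
  if (length(depth) < 2L) stop("curve needs at least 2 nodes", call. = FALSE)
  if (length(depth) != length(dose))
    stop("depth and dose lengths differ", call. = FALSE)
  if (is.unsorted(depth, strictly = TRUE))
    stop("depth grid must be strictly increasing", call. = FALSE)
  if (depth[1] != 0) stop("depth grid must start at 0", call. = FALSE)
  if (any(dose < 0) || any(!is.finite(dose)))
    stop("dose must be finite and >= 0", call. = FALSE)
  peak <- max(dose)
  idx <- which(dose > 1e-6 * peak)
  nominal_range <- if (length(idx)) depth[max(idx)] else 0
  # cumulative trapezoid at the nodes; exact integral of the piecewise-linear
  # curve is evaluated from this in C++ (shared with the transport loop)
  cum <- c(0, cumsum(diff(depth) * (dose[-1] + dose[-length(dose)]) / 2))
  structure(list(depth = depth, dose = dose, cum = cum,
                 nominal_range = nominal_range),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf(paste0("<depth_dose_curve> %d nodes, peak %.4g at %.1f mm, ",
                     "nominal range %.1f mm\n"),
              length(x$depth), max(x$dose), curve_peak_depth(x),
              x$nominal_range))
  invisible(x)
}

#' Depth of the Bragg peak of a curve
#' @param curve a `depth_dose_curve`.
#' @return mm water-equivalent depth of the curve maximum.
#' @export
curve_peak_depth <- function(curve) curve$depth[which.max(curve$dose)]

#' Analytic Bragg-curve generator
#'
#' Stand-in for a measured integral depth dose in water: a power-law pristine
#' stopping profile, dose proportional to (R - z)^(1/p - 1) below the range R
#' (p the range-energy exponent), convolved with a Gaussian range-straggling
#' kernel. R is calibrated iteratively so the argmax of the *convolved* curve
#' lands at `peak_depth_mm` (within one grid step). The curve is normalized
#' to peak 1.
#'
#' @param peak_depth_mm target Bragg-peak depth in mm (> 0).
#' @param straggling_sigma_mm Gaussian straggling width; default 1.2% of the
#'   peak depth, a realistic fractional range spread for therapeutic protons.
#' @param grid_step_mm tabulation step (default 0.5 mm, bounding the distal
#'   interpolation error of the engines).
#' @param p range-energy exponent (default 1.77).
#' @return a `depth_dose_curve`.
#' @examples
#' bc <- make_bragg_curve(150)
#' curve_peak_depth(bc)
#' @export
make_bragg_curve <- function(peak_depth_mm,
                             straggling_sigma_mm = 0.012 * peak_depth_mm,
                             grid_step_mm = 0.5, p = 1.77) {
  if (!is.finite(peak_depth_mm) || peak_depth_mm <= 0)
    stop("peak depth must be positive", call. = FALSE)
  if (straggling_sigma_mm < 0) stop("sigma must be >= 0", call. = FALSE)
  if (grid_step_mm <= 0) stop("grid step must be positive", call. = FALSE)
  h <- grid_step_mm
  sig <- straggling_sigma_mm
  build <- function(R) {
    zmax <- R + max(6 * sig, 2 * h) + 2 * h
    z <- seq(0, zmax, by = h)
    # cell-averaged pristine profile: mean of (R - u)^(1/p - 1) over the cell,
    # which stays finite across the divergence at u = R
    cexp <- 1 / p
    a <- pmin(pmax(z - h / 2, 0), R)
    b <- pmin(z + h / 2, R)
    f <- ifelse(b > a, ((R - a)^cexp - (R - b)^cexp) / (cexp * h), 0)
    if (sig > 0) {
      ko <- seq(-ceiling(5 * sig / h), ceiling(5 * sig / h))
      kern <- stats::dnorm(ko * h, sd = sig)
      kern <- kern / sum(kern)
      n <- length(f)
      # pad proximally with the (slowly varying) entrance value
      fp <- c(rep(f[1], length(ko)), f, rep(0, length(ko)))
      f <- vapply(seq_len(n), function(i) sum(fp[i + seq_along(ko) - 1] * kern),
                  0.0)
    }
    list(z = z, f = f)
  }
  R <- peak_depth_mm
  for (it in 1:6) {
    cur <- build(R)
    zpk <- cur$z[which.max(cur$f)]
    if (abs(zpk - peak_depth_mm) <= h / 2) break
    R <- R + (peak_depth_mm - zpk)
  }
  f <- cur$f
  # normalize the total integral (not the peak) to 100 arbitrary units, so
  # integrated quantities do not depend on the tabulation step
  tot <- sum(diff(cur$z) * (f[-1] + f[-length(f)]) / 2)
  f <- f * 100 / tot
  f[f < 1e-9 * max(f)] <- 0
  depth_dose_curve(cur$z, f)
}

#' Read / write a depth-dose curve as CSV
#'
#' Two-column CSV with header `depth_mm,dose`. A synthetic fixture curve
#' calibrated to peak at 257.5 mm in water (the heterogeneity benchmark's
#' calibration depth) ships with the package:
#' `system.file("extdata", "depth_dose_water_257.5mm.csv",
#' package = "smcproton")`.
#' @param path CSV path.
#' @return a `depth_dose_curve`.
#' @export
load_curve <- function(path) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("cannot parse depth-dose CSV: ", conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty depth-dose file", call. = FALSE)
  if (!all(c("depth_mm", "dose") %in% names(df)))
    stop("depth-dose CSV needs columns depth_mm,dose", call. = FALSE)
  depth_dose_curve(df$depth_mm, df$dose)
}

#' @rdname load_curve
#' @param curve a `depth_dose_curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(depth_mm = curve$depth, dose = curve$dose),
                   path, row.names = FALSE)
  invisible(path)
}

#' Integrated dose between two water-equivalent depths
#'
#' Exact integral of the piecewise-linear depth-dose curve over
#' `[w1, w2]` (the per-step deposit of the transport engine). Zero beyond the
#' curve's last node. Vectorized over `w1`/`w2`.
#'
#' @param curve a `depth_dose_curve`.
#' @param w1_mm,w2_mm depths in mm, `0 <= w1 <= w2`.
#' @return dose units (curve units times mm).
#' @export
dose_between <- function(curve, w1_mm, w2_mm) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  n <- max(length(w1_mm), length(w2_mm))
  w1 <- rep_len(as.numeric(w1_mm), n); w2 <- rep_len(as.numeric(w2_mm), n)
  if (any(w1 < 0) || any(w2 < w1))
    stop("need 0 <= w1 <= w2", call. = FALSE)
  curve_cum_cpp(curve$depth, curve$dose, curve$cum, w2) -
    curve_cum_cpp(curve$depth, curve$dose, curve$cum, w1)
}

#' Range-energy model (power law)
#'
#' Supplies the kinematic factor pv (momentum times velocity) needed by the
#' Highland scattering formula, from a proton's residual range in water via
#' the power-law range-energy relation R = alpha * E^p.
#'
#' @param energy_mev nominal beam energy used for calibration.
#' @param range_mm range in water assigned to that energy (typically the
#'   depth-dose curve's nominal range), so that `alpha = range_mm / energy^p`.
#' @param p range-energy exponent, default 1.77.
#' @param proton_rest_energy rest energy in MeV.
#' @return a `range_energy_model`.
#' @export
range_energy_model <- function(energy_mev, range_mm, p = 1.77,
                               proton_rest_energy = 938.272) {
  if (!(p > 1 && p < 2.2)) stop("p out of plausible range", call. = FALSE)
  if (energy_mev <= 0 || range_mm <= 0)
    stop("energy and range must be positive", call. = FALSE)
  alpha <- range_mm / energy_mev^p
  structure(list(alpha = alpha, p = p, energy_mev = energy_mev,
                 proton_rest_energy = proton_rest_energy),
            class = "range_energy_model")
}

#' pv from residual range
#'
#' Inverts the power-law range-energy relation to kinetic energy
#' `E = (r/alpha)^(1/p)` and returns `pv = E(E + 2m)/(E + m)` with m the
#' proton rest energy. Vectorized; returns 0 at r = 0.
#'
#' @param model a `range_energy_model`.
#' @param r_mm residual range(s) in mm water, >= 0.
#' @return pv in MeV.
#' @export
pv_from_residual_range <- function(model, r_mm) {
  stopifnot(inherits(model, "range_energy_model"))
  r <- as.numeric(r_mm)
  if (any(r < 0)) stop("residual range must be >= 0", call. = FALSE)
  E <- (r / model$alpha)^(1 / model$p)
  m <- model$proton_rest_energy
  E * (E + 2 * m) / (E + m)
}
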