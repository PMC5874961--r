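#' Multiple-Coulomb-scattering model constants
#'
#' Highland parameterization of the rms multiple-scattering angle in water:
#' theta0(w) = (14.1 MeV / pv) * sqrt(w / X0) * (1 + (1/9) log10(w / X0)),
#' with X0 the radiation length of water and the logarithmic factor floored
#' at 0 for very thin cumulative thickness.
#'
#' @param highland_constant MeV, default 14.1.
#' @param X0_water radiation length of water in mm, default 360.8.
#' @param log_correction apply the (1 + (1/9) log10) factor on cumulative
#'   thickness (default TRUE).
#' @return a `scattering_model`.
#' @export
scattering_model <- function(highland_constant = 14.1, X0_water = 360.8,
                             log_correction = TRUE) {
  if (highland_constant <= 0 || X0_water <= 0)
    stop("scattering constants must be positive", call. = FALSE)
  structure(list(highland_constant = highland_constant, X0_water = X0_water,
                 log_correction = isTRUE(log_correction)),
            class = "scattering_model")
}

#' Cumulative Highland angle
#'
#' theta0 for a proton of kinematic factor `pv` after traversing `w_mm` of
#' water. Vectorized.
#' @param model a `scattering_model`.
#' @param pv_MeV kinematic factor pv in MeV (> 0).
#' @param w_mm cumulative water-equivalent thickness in mm (>= 0).
#' @return rms angle in rad.
#' @export
highland_theta0 <- function(model, pv_MeV, w_mm) {
  stopifnot(inherits(model, "scattering_model"))
  if (any(pv_MeV <= 0)) stop("pv must be positive", call. = FALSE)
  w <- pmax(as.numeric(w_mm), 0)
  f <- if (model$log_correction) {
    pmax(1 + log10(pmax(w, .Machine$double.xmin) / model$X0_water) / 9, 0)
  } else 1
  ifelse(w > 0,
         (model$highland_constant / pv_MeV) * sqrt(w / model$X0_water) * f,
         0)
}

#' Per-step Highland scattering kick
#'
#' The per-step rms kick is defined by difference-in-quadrature of the
#' cumulative Highland angle, so kicks telescope: summing step variances over
#' any partition of \[0, W\] reproduces theta0(W)^2 exactly and the angular
#' spread is step-size independent.
#'
#' @param model a `scattering_model`.
#' @param pv_MeV kinematic factor pv in MeV.
#' @param cum_wet_mm water-equivalent depth already traversed, mm.
#' @param step_wet_mm water-equivalent thickness of this step, mm.
#' @return rms kick in rad (0 for a zero-length step).
#' @export
highland_sigma <- function(model, pv_MeV, cum_wet_mm, step_wet_mm) {
  t2 <- highland_theta0(model, pv_MeV, cum_wet_mm + step_wet_mm)^2 -
    highland_theta0(model, pv_MeV, cum_wet_mm)^2
  sqrt(pmax(t2, 0))
}

#' Dose grid
#'
#' A 3D dose distribution sharing the geometry conventions of [voxel_grid()].
#' @param dose 3D numeric array (>= 0, finite).
#' @param spacing,origin grid geometry in mm.
#' @return a `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, origin) {
  if (length(dim(dose)) != 3L) stop("dose must be a 3D array", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and >= 0", call. = FALSE)
  structure(list(dose = dose, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, total %.6g, max %.6g\n",
              d[1], d[2], d[3], sum(x$dose), max(x$dose)))
  invisible(x)
}

#' Simplified Monte Carlo proton transport
#'
#' Tracks each proton of an ensemble through the voxel grid. Per z-step of
#' one voxel: the water-equivalent step is dz * rsp * sqrt(1 + tx^2 + ty^2)
#' evaluated in the voxel containing the step midpoint; the deposit is the
#' depth-dose curve integral over \[w, w + dw\] scored in that voxel; the
#' projection angles then receive independent Gaussian Highland kicks with pv
#' evaluated at the proton's current residual range (nominal range minus w).
#' Protons terminate when w reaches the curve's nominal range or when they
#' leave the grid laterally (their remaining dose is lost). Nuclear
#' interactions and explicit energy straggling are not simulated; both are
#' folded into the depth-dose curve.
#'
#' @param ensemble a `proton_ensemble` at (or upstream of) the entrance face.
#' @param grid a `voxel_grid`.
#' @param curve a `depth_dose_curve`.
#' @param range_model a `range_energy_model` (pv lookup).
#' @param scattering a `scattering_model`.
#' @param rs_wet_mm initial water-equivalent depth already consumed upstream
#'   (the range shifter's water-equivalent thickness).
#' @param max_kick_sigma cap on the per-step kick rms, rad.
#' @param max_angle clamp on |tx|, |ty| (small-angle validity bound), rad.
#' @return a `dose_grid` with dose summed over protons (not normalized).
#' @export
transport <- function(ensemble, grid, curve, range_model,
                      scattering = scattering_model(), rs_wet_mm = 0,
                      max_kick_sigma = 0.1, max_angle = 0.3) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(curve, "depth_dose_curve"),
            inherits(range_model, "range_energy_model"),
            inherits(scattering, "scattering_model"))
  if (rs_wet_mm < 0) stop("rs_wet_mm must be >= 0", call. = FALSE)
  if (rs_wet_mm >= curve$nominal_range)
    stop("range shifter thicker than the proton range", call. = FALSE)
  d <- dim(grid$rsp)
  dose <- transport_cpp(
    grid$rsp, as.integer(d), grid$spacing, grid$origin,
    ensemble$x, ensemble$y, ensemble$z, ensemble$tx, ensemble$ty,
    curve$depth, curve$dose, curve$cum, curve$nominal_range,
    range_model$alpha, range_model$p, range_model$proton_rest_energy,
    scattering$highland_constant, scattering$X0_water,
    scattering$log_correction, rs_wet_mm, max_kick_sigma, max_angle)
  dim(dose) <- d
  dose_grid(dose, grid$spacing, grid$origin)
}

#' Default range-energy model for a spot + curve pair
#'
#' Calibrates alpha so the model range at the spot's nominal energy equals
#' the curve's nominal range, keeping Highland's pv consistent with the
#' supplied depth-dose curve.
#' @param spot a `spot`.
#' @param curve a `depth_dose_curve`.
#' @return a `range_energy_model`.
#' @export
default_range_model <- function(spot, curve) {
  range_energy_model(spot$energy, curve$nominal_range)
}

#' Compute a per-spot SMC dose kernel
#'
#' Samples the spot's initial ensemble from the effective source model,
#' applies the range shifter's energy loss as an initial water-equivalent
#' depth offset, transports through the grid, and normalizes to dose per
#' source proton.
#'
#' @param spot a `spot`.
#' @param grid a `voxel_grid`.
#' @param curve a `depth_dose_curve`.
#' @param source_table a `source_table`.
#' @param n number of protons (>= 1).
#' @param seed integer seed (bit-identical kernels for identical inputs).
#' @param range_model optional `range_energy_model`; default calibrated from
#'   the spot energy and curve range.
#' @param scattering a `scattering_model`.
#' @param entrance_z,iso_z geometry passed to [sample_spot_protons()].
#' @param rs_in_curve set TRUE when the depth-dose curve was measured (or
#'   calibrated) downstream of the range shifter, so its energy loss is
#'   already part of the curve and no initial water-equivalent offset is
#'   applied; default FALSE (pristine bare-beam curve, the range shifter
#'   consumes `rs_wet(rs)` of range up front).
#' @return a `dose_kernel`: a `dose_grid` plus `spot`, `n_protons`, `seed`.
#' @export
compute_kernel <- function(spot, grid, curve, source_table, n, seed = 1L,
                           range_model = NULL,
                           scattering = scattering_model(),
                           entrance_z = 0, iso_z = 0, rs_in_curve = FALSE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  src <- lookup_source(source_table, spot$rs_thickness)
  if (is.null(range_model)) range_model <- default_range_model(spot, curve)
  ens <- sample_spot_protons(src, spot, n, seed = seed,
                             entrance_z = entrance_z, iso_z = iso_z)
  dg <- transport(ens, grid, curve, range_model, scattering,
                  rs_wet_mm = if (rs_in_curve) 0 else
                    rs_wet(spot$rs_thickness))
  dg$dose <- dg$dose / n
  structure(c(unclass(dg),
              list(spot = spot, n_protons = as.integer(n), seed = seed)),
            class = c("dose_kernel", "dose_grid"))
}

#' Persist / load a dose kernel (MHD volume + JSON sidecar)
#' @param kernel a `dose_kernel`.
#' @param path_prefix output path without extension.
#' @return the `.mhd` path (write) or a `dose_kernel` (read), invisibly.
#' @export
write_kernel <- function(kernel, path_prefix) {
  mhd <- write_mhd(kernel, paste0(path_prefix, ".mhd"))
  meta <- list(spot = unclass(kernel$spot), n_protons = kernel$n_protons,
               seed = kernel$seed)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mhd)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path_prefix) {
  dg <- read_mhd(paste0(path_prefix, ".mhd"), as = "dose_grid")
  meta <- jsonlite::fromJSON(paste0(path_prefix, ".json"))
  sp <- do.call(spot, meta$spot[c("x_iso", "y_iso", "energy", "rs_thickness",
                                  "layer_wed", "weight")])
  structure(c(unclass(dg), list(spot = sp,
                                n_protons = as.integer(meta$n_protons),
                                seed = meta$seed)),
            class = c("dose_kernel", "dose_grid"))
}

#' Batch estimate of the Monte Carlo statistical error
#'
#' Splits the protons of a spot into equal batches, recomputes the masked
#' dose per batch, and reports the mean over mask voxels of the per-voxel
#' standard error of the batch mean (rms of batch deviations divided by
#' sqrt(batches)), as a percentage of the maximum mean dose in the mask.
#'
#' @param spot,grid,curve,source_table,seed as in [compute_kernel()].
#' @param mask logical array over the grid (non-empty).
#' @param n total number of protons.
#' @param batches number of batches (>= 2).
#' @param ... passed to [compute_kernel()].
#' @return percent of the masked maximum dose.
#' @export
estimate_statistical_error <- function(spot, grid, curve, source_table, mask,
                                       n, batches = 10, seed = 1L, ...) {
  if (batches < 2) stop("need at least 2 batches", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  nb <- as.integer(floor(n / batches))
  vals <- vapply(seq_len(batches), function(b) {
    k <- compute_kernel(spot, grid, curve, source_table, nb,
                        seed = spot_seed(seed, b), ...)
    k$dose[mask]
  }, numeric(sum(mask)))
  batch_statistical_error(vals)
}

#' Statistical error from a voxel-by-batch dose matrix
#'
#' Core of [estimate_statistical_error()], usable with externally computed
#' batch doses: rows are mask voxels, columns are batches.
#' @param batch_values numeric matrix (voxels x batches).
#' @return percent of the maximum mean dose over the voxels.
#' @export
batch_statistical_error <- function(batch_values) {
  b <- ncol(batch_values)
  if (is.null(b) || b < 2) stop("need >= 2 batches", call. = FALSE)
  mean_dose <- rowMeans(batch_values)
  mx <- max(mean_dose)
  if (mx <= 0) stop("all-zero dose in the mask", call. = FALSE)
  rms <- sqrt(rowMeans((batch_values - mean_dose)^2))
  100 * mean(rms / sqrt(b)) / mx
}
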