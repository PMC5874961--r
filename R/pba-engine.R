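#' Pencil-beam-algorithm configuration
#'
#' @param n_subspots 1 (single central axis) or a perfect square (e.g. 121 =
#'   11 x 11): the source spatial Gaussian is decomposed into parallel
#'   subspot axes so lateral heterogeneity across the beam is partially
#'   resolved.
#' @param lateral_cutoff_sigma truncation radius of the lateral Gaussians in
#'   units of sigma (>= 3).
#' @return a `pba_config`.
#' @export
pba_config <- function(n_subspots = 1, lateral_cutoff_sigma = 4) {
  k <- sqrt(n_subspots)
  if (n_subspots < 1 || abs(k - round(k)) > 1e-9)
    stop("n_subspots must be a perfect square", call. = FALSE)
  if (lateral_cutoff_sigma < 3)
    stop("lateral_cutoff_sigma must be >= 3", call. = FALSE)
  structure(list(n_subspots = as.integer(n_subspots),
                 lateral_cutoff_sigma = lateral_cutoff_sigma),
            class = "pba_config")
}

#' Cumulative water-equivalent depth along a beam-parallel axis
#'
#' Straight-path WET accumulation through the voxel column containing the
#' axis — the quantity on which the whole PBA rests (and its central
#' limitation: heterogeneity is only seen on this one path).
#'
#' @param grid a `voxel_grid`.
#' @param x,y lateral axis position in mm (or a `spot`, whose
#'   x_iso/y_iso are used).
#' @return data.frame with `z` (geometric depth of each voxel exit face, mm)
#'   and `wet` (cumulative water-equivalent depth, mm).
#' @export
central_axis_wed_profile <- function(grid, x, y = NULL) {
  if (inherits(x, "spot")) { y <- x$y_iso; x <- x$x_iso }
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$rsp)
  ij <- axis_voxel(grid, x, y)
  if (is.null(ij)) stop("axis does not intersect the grid", call. = FALSE)
  dz <- grid$spacing[3]
  col <- grid$rsp[ij[1], ij[2], ]
  z0 <- grid$origin[3] - dz / 2
  data.frame(z = z0 + seq_len(d[3]) * dz, wet = cumsum(col * dz))
}

# voxel (i, j) containing a beam-parallel axis, or NULL when outside
axis_voxel <- function(grid, x, y) {
  d <- dim(grid$rsp)
  i <- floor((x - (grid$origin[1] - grid$spacing[1] / 2)) / grid$spacing[1]) + 1
  j <- floor((y - (grid$origin[2] - grid$spacing[2] / 2)) / grid$spacing[2]) + 1
  if (i < 1 || i > d[1] || j < 1 || j > d[2]) return(NULL)
  c(i, j)
}

#' Fermi-Eyges multiple-scattering lateral variance along an axis
#'
#' Accumulates the Highland scattering power along the straight axis and
#' returns the multiple-Coulomb-scattering contribution to the lateral dose
#' variance at each voxel-center depth z:
#' sigma_mcs^2(z) = sum over upstream slabs of (z - u)^2 * dtheta0^2(u),
#' with the per-slab kick variance telescoped in quadrature exactly as in the
#' Monte Carlo engine (same scattering power).
#'
#' @param grid a `voxel_grid`.
#' @param x,y axis position, mm.
#' @param curve a `depth_dose_curve`.
#' @param range_model a `range_energy_model`.
#' @param scattering a `scattering_model`.
#' @param rs_wet_mm upstream water-equivalent offset, mm.
#' @return data.frame with `z` (voxel centers, mm), `w` (WED at slab entry)
#'   and `var_mcs` (mm^2).
#' @export
fermi_eyges_mcs_variance <- function(grid, x, y, curve, range_model,
                                     scattering = scattering_model(),
                                     rs_wet_mm = 0) {
  ij <- axis_voxel(grid, x, y)
  if (is.null(ij)) stop("axis does not intersect the grid", call. = FALSE)
  dz <- grid$spacing[3]
  col <- grid$rsp[ij[1], ij[2], ]
  nz <- length(col)
  w_exit <- rs_wet_mm + cumsum(col * dz)
  w_in <- c(rs_wet_mm, w_exit[-nz])
  r_in <- curve$nominal_range - w_in
  dth2 <- numeric(nz)
  live <- r_in > 0 & col > 0
  if (any(live)) {
    pv <- pv_from_residual_range(range_model, r_in[live])
    ok <- pv > 0
    idx <- which(live)[ok]
    # cap the slab WET at the residual range so the last slab's kick stays
    # finite, mirroring the transport termination
    wend <- pmin(w_exit[idx], curve$nominal_range)
    dth2[idx] <- pmax(
      highland_theta0(scattering, pv[ok], wend)^2 -
        highland_theta0(scattering, pv[ok], w_in[idx])^2, 0)
  }
  u <- grid$origin[3] + (seq_len(nz) - 1) * dz   # slab midpoints
  a0 <- c(0, cumsum(dth2))[seq_len(nz)]
  a1 <- c(0, cumsum(u * dth2))[seq_len(nz)]
  a2 <- c(0, cumsum(u^2 * dth2))[seq_len(nz)]
  z <- u
  data.frame(z = z, w = w_in, var_mcs = pmax(z^2 * a0 - 2 * z * a1 + a2, 0))
}

#' Fermi-Eyges prediction of the lateral beam sigma in a phantom
#'
#' Total lateral rms of the dose profile at depth z for a spot: drifted
#' effective-source contribution (spatial spread plus angular spread times
#' the per-axis source distance lever arm) plus the Fermi-Eyges
#' multiple-scattering variance along the axis. This is the closed-form
#' counterpart of the Monte Carlo lateral spread in a laterally homogeneous
#' medium.
#'
#' @inheritParams fermi_eyges_mcs_variance
#' @param source an `effective_source`.
#' @param iso_z isocenter plane z, mm (default 0 = entrance face).
#' @return data.frame with `z`, `sigma_x`, `sigma_y` (mm).
#' @export
fermi_eyges_sigma <- function(grid, x, y, curve, source, range_model,
                              scattering = scattering_model(),
                              rs_wet_mm = 0, iso_z = 0) {
  fe <- fermi_eyges_mcs_variance(grid, x, y, curve, range_model, scattering,
                                 rs_wet_mm)
  dx_ <- fe$z - (iso_z - source$L_x)
  dy_ <- fe$z - (iso_z - source$L_y)
  data.frame(
    z = fe$z,
    sigma_x = sqrt(source$sigma_x^2 + (dx_ * source$sigma_tx * 1e-3)^2 +
                     fe$var_mcs),
    sigma_y = sqrt(source$sigma_y^2 + (dy_ * source$sigma_ty * 1e-3)^2 +
                     fe$var_mcs))
}

#' Analytical pencil-beam dose kernel
#'
#' Reference comparator for the Monte Carlo engine: along each (sub)spot
#' axis the water-equivalent depth is accumulated on the straight central
#' path only, the depth-dose curve supplies the per-slab deposit, and the
#' lateral distribution is the product of normalized 1D Gaussians whose
#' variance is the drifted-source contribution plus the Fermi-Eyges
#' multiple-scattering variance (same Highland scattering power as the SMC
#' engine). With `n_subspots > 1` the source spatial Gaussian is decomposed
#' into a square grid of parallel subspot axes over +/- 3 sigma with
#' product-Gaussian weights, which partially restores sensitivity to lateral
#' heterogeneity.
#'
#' By construction the kernel is exactly mirror-symmetric about each subspot
#' axis whatever the phantom — the PBA's defining limitation.
#'
#' @inheritParams compute_kernel
#' @param config a `pba_config`.
#' @return a `dose_kernel` (per-proton normalization, `n_protons = NA`).
#' @export
pba_kernel <- function(spot, grid, curve, source_table,
                       config = pba_config(), range_model = NULL,
                       scattering = scattering_model(), iso_z = 0,
                       rs_in_curve = FALSE) {
  stopifnot(inherits(config, "pba_config"))
  src <- lookup_source(source_table, spot$rs_thickness)
  if (is.null(range_model)) range_model <- default_range_model(spot, curve)
  rswet <- if (rs_in_curve) 0 else rs_wet(spot$rs_thickness)
  d <- dim(grid$rsp)
  dzv <- grid$spacing[3]
  xs <- voxel_centers(grid, 1); ys <- voxel_centers(grid, 2)
  dose <- array(0, dim = d)

  k <- as.integer(round(sqrt(config$n_subspots)))
  if (k == 1L) {
    off_x <- 0; off_y <- 0; wts <- matrix(1, 1, 1)
    cell_var_x <- src$sigma_x^2; cell_var_y <- src$sigma_y^2
  } else {
    nod_x <- seq(-3 * src$sigma_x, 3 * src$sigma_x, length.out = k)
    nod_y <- seq(-3 * src$sigma_y, 3 * src$sigma_y, length.out = k)
    wx <- stats::dnorm(nod_x, sd = src$sigma_x)
    wy <- stats::dnorm(nod_y, sd = src$sigma_y)
    wts <- outer(wx / sum(wx), wy / sum(wy))
    off_x <- nod_x; off_y <- nod_y
    cell_var_x <- diff(nod_x[1:2])^2 / 12
    cell_var_y <- diff(nod_y[1:2])^2 / 12
  }
  dist_x <- (grid$origin[3] + (seq_len(d[3]) - 1) * dzv) - (iso_z - src$L_x)
  dist_y <- (grid$origin[3] + (seq_len(d[3]) - 1) * dzv) - (iso_z - src$L_y)
  cutoff <- config$lateral_cutoff_sigma

  for (a in seq_along(off_x)) for (b in seq_along(off_y)) {
    ax <- spot$x_iso + off_x[a]; ay <- spot$y_iso + off_y[b]
    ij <- axis_voxel(grid, ax, ay)
    if (is.null(ij)) next  # subspot axis misses the grid entirely
    fe <- fermi_eyges_mcs_variance(grid, ax, ay, curve, range_model,
                                   scattering, rs_wet_mm = rswet)
    col <- grid$rsp[ij[1], ij[2], ]
    w_exit <- rswet + cumsum(col * dzv)
    w_in <- c(rswet, w_exit[-d[3]])
    dep <- dose_between(curve, pmin(w_in, w_exit), w_exit)
    sx <- sqrt(cell_var_x + (dist_x * src$sigma_tx * 1e-3)^2 + fe$var_mcs)
    sy <- sqrt(cell_var_y + (dist_y * src$sigma_ty * 1e-3)^2 + fe$var_mcs)
    wab <- wts[a, b]
    for (iz in which(dep > 0)) {
      ixr <- which(abs(xs - ax) <= cutoff * sx[iz])
      iyr <- which(abs(ys - ay) <= cutoff * sy[iz])
      if (!length(ixr) || !length(iyr)) next
      gx <- stats::dnorm(xs[ixr], ax, sx[iz]) * grid$spacing[1]
      gy <- stats::dnorm(ys[iyr], ay, sy[iz]) * grid$spacing[2]
      dose[ixr, iyr, iz] <- dose[ixr, iyr, iz] + (wab * dep[iz]) * outer(gx, gy)
    }
  }
  dg <- dose_grid(dose, grid$spacing, grid$origin)
  structure(c(unclass(dg),
              list(spot = spot, n_protons = NA_integer_, seed = NA_integer_)),
            class = c("dose_kernel", "dose_grid"))
}
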