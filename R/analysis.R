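#' Laterally integrated depth dose
#'
#' Per-depth sum of the dose over the transverse plane: the integral
#' depth-dose curve of a dose grid. Summing the returned dose over z gives
#' the total dose in the grid.
#'
#' @param dose_grid a `dose_grid`.
#' @return data.frame with `z` (voxel-center depth, mm) and `dose`.
#' @export
laterally_integrated_depth_dose <- function(dose_grid) {
  stopifnot(inherits(dose_grid, "dose_grid"))
  d <- dim(dose_grid$dose)
  data.frame(z = voxel_centers(dose_grid, 3),
             dose = colSums(matrix(dose_grid$dose, ncol = d[3])))
}

#' Local maxima of a depth-dose curve
#'
#' Peak finder for Bragg-peak tables: a point is a candidate peak when it is
#' the maximum within a +/- `window` index neighborhood, at least
#' `min_height_frac` of the global maximum; of two adjacent candidates not
#' separated by a valley dipping `min_prominence_frac` of the global maximum
#' below the smaller one, only the higher survives.
#'
#' @param z positions (mm).
#' @param dose values.
#' @param window half-width of the local-max neighborhood, in samples.
#' @param min_height_frac minimum peak height, fraction of max.
#' @param min_prominence_frac minimum valley drop, fraction of max.
#' @return data.frame with `z` and `dose` of each peak, ordered by z.
#' @export
find_peaks <- function(z, dose, window = 5L, min_height_frac = 0.1,
                       min_prominence_frac = 0.05) {
  n <- length(dose)
  mx <- max(dose)
  cand <- integer()
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    # window maximum, first index on a plateau
    if (i == lo - 1L + which.max(dose[lo:hi]) && dose[i] >= min_height_frac * mx)
      cand <- c(cand, i)
  }
  # collapse plateau/near-duplicate candidates and weak shoulders
  keep <- cand
  repeat {
    if (length(keep) < 2L) break
    drop <- integer()
    for (j in seq_len(length(keep) - 1L)) {
      i1 <- keep[j]; i2 <- keep[j + 1L]
      valley <- min(dose[i1:i2])
      if (valley > min(dose[i1], dose[i2]) - min_prominence_frac * mx) {
        drop <- c(drop, if (dose[i1] >= dose[i2]) j + 1L else j)
        break
      }
    }
    if (!length(drop)) break
    keep <- keep[-drop]
  }
  data.frame(z = z[keep], dose = dose[keep])
}

#' RMS relative dose difference
#'
#' `100 * sqrt(mean((a - b)^2 over the region)) / max(b over the region)`:
#' the rms of the voxelwise difference normalized to the maximum of the
#' *second* argument (the reference) in the region. Not symmetric in its
#' arguments — the normalizer is always `dose_b`.
#'
#' @param dose_a,dose_b `dose_grid`s or arrays on the same grid.
#' @param region_mask logical array (non-empty).
#' @return percent.
#' @export
rms_relative_difference <- function(dose_a, dose_b, region_mask = NULL) {
  a <- if (inherits(dose_a, "dose_grid")) dose_a$dose else dose_a
  b <- if (inherits(dose_b, "dose_grid")) dose_b$dose else dose_b
  if (!identical(dim(a), dim(b)))
    stop("dose grids have different dimensions", call. = FALSE)
  if (is.null(region_mask)) region_mask <- array(TRUE, dim = dim(a))
  if (!any(region_mask)) stop("empty region", call. = FALSE)
  bm <- max(b[region_mask])
  if (bm <= 0) stop("reference dose is zero in the region", call. = FALSE)
  100 * sqrt(mean((a[region_mask] - b[region_mask])^2)) / bm
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction (percent of the structure) receiving at least each dose
#' level, with the dose axis in percent of the prescription.
#'
#' @param dose_grid a `dose_grid` or array.
#' @param mask logical array (non-empty).
#' @param prescription dose corresponding to 100%.
#' @param bin_percent dose-axis bin width, percent.
#' @return a `dvh_curve` data.frame with `dose_percent` and `volume_percent`
#'   (non-increasing, starting at 100).
#' @export
dvh <- function(dose_grid, mask, prescription, bin_percent = 0.1) {
  d <- if (inherits(dose_grid, "dose_grid")) dose_grid$dose else dose_grid
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (prescription <= 0) stop("prescription must be positive", call. = FALSE)
  v <- 100 * d[mask] / prescription
  axis <- seq(0, max(v) + bin_percent, by = bin_percent)
  vol <- vapply(axis, function(t) 100 * mean(v >= t), 0.0)
  structure(data.frame(dose_percent = axis, volume_percent = vol),
            class = c("dvh_curve", "data.frame"))
}

#' Dose at volume (DVH quantile)
#'
#' Dx: the dose (percent of prescription) received by at least `q_percent`
#' of the structure — the dose at which the cumulative DVH crosses
#' `q_percent`, linearly interpolated between bins.
#'
#' @param dvh_curve a `dvh_curve`.
#' @param q_percent volume level in (0, 100), e.g. 95 for D95.
#' @return dose in percent of prescription.
#' @export
d_at_volume <- function(dvh_curve, q_percent) {
  if (q_percent <= 0 || q_percent >= 100)
    stop("q_percent must be in (0, 100)", call. = FALSE)
  vol <- dvh_curve$volume_percent
  dx <- dvh_curve$dose_percent
  i <- which(vol < q_percent)[1]
  if (is.na(i)) return(dx[length(dx)])
  if (i == 1L) return(dx[1])
  # linear interpolation across the crossing bin
  v1 <- vol[i - 1L]; v2 <- vol[i]
  if (v1 == v2) return(dx[i])
  dx[i - 1L] + (dx[i] - dx[i - 1L]) * (v1 - q_percent) / (v1 - v2)
}

#' Gamma-index comparison
#'
#' Global-normalization gamma: for every evaluated voxel at or above the dose
#' cutoff (fraction of the reference maximum), the minimum over a +/- 2*dta
#' search window (half-voxel sampling of the trilinearly interpolated
#' reference) of sqrt(dr^2/dta^2 + dD^2/(dd% of max ref)^2). Reports the
#' percentage of analyzed voxels with gamma <= 1.
#'
#' @param reference,evaluated `dose_grid`s on the same grid.
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param dd_percent dose-difference criterion, percent of the reference max.
#' @param dose_cutoff_percent exclusion threshold, percent of the reference
#'   max (voxels with reference dose below it are not analyzed).
#' @return list with `pass_rate` (percent), `gamma` (array, NA below
#'   cutoff), `n_analyzed`.
#' @export
gamma_index <- function(reference, evaluated, dta_mm = 3, dd_percent = 3,
                        dose_cutoff_percent = 10) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (!identical(dim(reference$dose), dim(evaluated$dose)))
    stop("dose grids have different dimensions", call. = FALSE)
  if (dta_mm <= 0 || dd_percent <= 0)
    stop("criteria must be positive", call. = FALSE)
  mx <- max(reference$dose)
  cutoff <- dose_cutoff_percent / 100 * mx
  if (all(reference$dose < cutoff) || mx <= 0)
    stop("all voxels below the dose cutoff", call. = FALSE)
  sub <- min(reference$spacing) / 2
  g <- gamma_cpp(reference$dose, evaluated$dose, dim(reference$dose),
                 reference$spacing, reference$origin, dta_mm,
                 dd_percent / 100 * mx, cutoff, 2 * dta_mm, sub)
  dim(g) <- dim(reference$dose)
  analyzed <- !is.na(g)
  list(pass_rate = 100 * mean(g[analyzed] <= 1),
       gamma = g, n_analyzed = sum(analyzed))
}

#' Isodose / difference report for one plane
#'
#' Writes side-by-side isodose maps of two dose grids and their difference
#' on a y-plane (x-z maps): a PNG with three panels plus CSVs of the three
#' slices. The difference is `a - b`.
#'
#' @param dose_a,dose_b `dose_grid`s on the same grid.
#' @param plane y voxel index of the slice (default: central plane).
#' @param path_prefix output path prefix (files `<prefix>.png`,
#'   `<prefix>_{a,b,diff}.csv`).
#' @return named character vector of the written files, invisibly.
#' @export
export_isodose_report <- function(dose_a, dose_b, plane = NULL, path_prefix) {
  stopifnot(inherits(dose_a, "dose_grid"), inherits(dose_b, "dose_grid"))
  if (!identical(dim(dose_a$dose), dim(dose_b$dose)))
    stop("dose grids have different dimensions", call. = FALSE)
  d <- dim(dose_a$dose)
  if (is.null(plane)) plane <- (d[2] + 1L) %/% 2L
  if (plane < 1 || plane > d[2]) stop("invalid plane index", call. = FALSE)
  sa <- dose_a$dose[, plane, ]
  sb <- dose_b$dose[, plane, ]
  sdiff <- sa - sb
  files <- c(png = paste0(path_prefix, ".png"),
             a = paste0(path_prefix, "_a.csv"),
             b = paste0(path_prefix, "_b.csv"),
             diff = paste0(path_prefix, "_diff.csv"))
  utils::write.csv(sa, files["a"], row.names = FALSE)
  utils::write.csv(sb, files["b"], row.names = FALSE)
  utils::write.csv(sdiff, files["diff"], row.names = FALSE)
  xs <- voxel_centers(dose_a, 1); zs <- voxel_centers(dose_a, 3)
  grDevices::png(files["png"], width = 1500, height = 500)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (panel in list(list(sa, "dose A"), list(sb, "dose B"),
                     list(sdiff, "A - B"))) {
    graphics::image(xs, zs, panel[[1]], xlab = "x (mm)", ylab = "z (mm)",
                    main = panel[[2]], useRaster = TRUE)
    graphics::contour(xs, zs, panel[[1]], add = TRUE, nlevels = 8)
  }
  invisible(files)
}
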