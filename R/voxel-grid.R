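#' Voxelized relative-stopping-power grid
#'
#' A `voxel_grid` is the patient/phantom model used by all dose engines: a 3D
#' array of relative stopping power (rsp, water = 1) on a regular lattice.
#' The beam travels along +z. By convention x and y are centered on the beam
#' axis (x = y = 0 at the lateral grid center) and z is depth measured from
#' the phantom entrance face, so the first voxel layer spans z in [0, dz).
#' `origin` is the position of the center of voxel (1,1,1).
#'
#' @param rsp 3D numeric array of relative stopping power (>= 0, finite).
#' @param spacing numeric length-3, voxel size in mm (dx, dy, dz), all > 0.
#' @param origin numeric length-3, mm position of the first voxel center.
#'   Default centers the grid laterally and puts the entrance face at z = 0.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(rsp, spacing, origin = NULL) {
  if (length(dim(rsp)) != 3L)
    stop("rsp must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  if (any(!is.finite(rsp)) || any(rsp < 0))
    stop("rsp values must be finite and >= 0", call. = FALSE)
  d <- dim(rsp)
  if (is.null(origin)) {
    origin <- c(-(d[1] - 1) / 2 * spacing[1],
                -(d[2] - 1) / 2 * spacing[2],
                spacing[3] / 2)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(rsp = rsp, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$rsp)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  rsp range [%.4g, %.4g], origin (%s) mm\n",
              min(x$rsp), max(x$rsp),
              paste(signif(x$origin, 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$rsp)

#' Voxel center coordinates along one axis
#' @param grid a `voxel_grid` or `dose_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel center positions in mm.
#' @export
voxel_centers <- function(grid, axis) {
  n <- dim(grid$rsp %||% grid$dose)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uniform water tank phantom
#'
#' Builds a rectangular water phantom (rsp = 1 everywhere). Voxel counts are
#' `round(dims_mm / spacing_mm)`.
#'
#' @param dims_mm physical size in mm, length 3 (x, y, z).
#' @param spacing_mm voxel size in mm; scalar or length 3.
#' @return a `voxel_grid`.
#' @examples
#' tank <- make_water_tank(c(100, 100, 150), 2)
#' dim(tank)
#' @export
make_water_tank <- function(dims_mm, spacing_mm = 1) {
  dims_mm <- as.numeric(dims_mm)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  if (length(dims_mm) != 3L || any(!is.finite(dims_mm)) || any(dims_mm <= 0))
    stop("dims_mm must be 3 positive numbers", call. = FALSE)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be positive", call. = FALSE)
  n <- pmax(1L, as.integer(round(dims_mm / spacing_mm)))
  voxel_grid(array(1.0, dim = n), spacing_mm)
}

#' Generic slab phantom builder
#'
#' Water tank with rectangular blocks of arbitrary stopping power inserted.
#' Block extents are half-open intervals `[lo, hi)`; a voxel belongs to a
#' block iff its center lies inside. x and y are mm relative to the beam
#' axis, z is depth from the entrance face.
#'
#' @param dims_mm,spacing_mm as in [make_water_tank()].
#' @param slabs list of lists with elements `x`, `y`, `z` (length-2 mm
#'   intervals) and `rsp` (scalar).
#' @return a `voxel_grid`.
#' @export
make_slab_phantom <- function(dims_mm, spacing_mm = 1, slabs = list()) {
  g <- make_water_tank(dims_mm, spacing_mm)
  xs <- voxel_centers(g, 1); ys <- voxel_centers(g, 2); zs <- voxel_centers(g, 3)
  for (s in slabs) {
    ix <- which(xs >= s$x[1] & xs < s$x[2])
    iy <- which(ys >= s$y[1] & ys < s$y[2])
    iz <- which(zs >= s$z[1] & zs < s$z[2])
    if (length(ix) && length(iy) && length(iz))
      g$rsp[ix, iy, iz] <- s$rsp
  }
  g
}

#' Bone/lung benchmark phantom
#'
#' The standard heterogeneity benchmark: a 300 x 300 x 400 mm water tank at
#' 1 mm voxels containing two 10 x 20 x 50 mm blocks side by side, a
#' bone-like block at x in [-10, 0) and a lung-like block at x in [0, 10)
#' (interface on the beam axis), both y in [-10, 10), entrance faces at
#' 150 mm depth. The default block stopping powers place the bone-path Bragg
#' peak 23 mm shallower and the lung-path peak 39 mm deeper than the
#' water-path peak.
#'
#' @param bone_rsp relative stopping power of the bone block (> 1).
#' @param lung_rsp relative stopping power of the lung block (in (0, 1)).
#' @return list with elements `grid` (a `voxel_grid`) and `slabs`
#'   (block metadata).
#' @export
make_benchmark_phantom <- function(bone_rsp = 1.46, lung_rsp = 0.217) {
  if (!(bone_rsp > 1 && 1 > lung_rsp && lung_rsp > 0))
    stop("need bone_rsp > 1 > lung_rsp > 0", call. = FALSE)
  slabs <- list(
    list(x = c(-10, 0), y = c(-10, 10), z = c(150, 200), rsp = bone_rsp,
         name = "bone"),
    list(x = c(0, 10),  y = c(-10, 10), z = c(150, 200), rsp = lung_rsp,
         name = "lung"))
  g <- make_slab_phantom(c(300, 300, 400), 1, slabs)
  list(grid = g, slabs = slabs)
}

#' CT-number to stopping-power calibration table
#'
#' Piecewise-linear mapping from CT numbers (HU-like) to relative stopping
#' power. Node CT numbers must be strictly increasing, rsp non-negative, and
#' the table must map 0 to exactly 1 (the water anchor).
#'
#' @param ct_number,rsp numeric vectors of equal length.
#' @return a `calibration_table` (data.frame).
#' @export
calibration_table <- function(ct_number, rsp) {
  ct_number <- as.numeric(ct_number); rsp <- as.numeric(rsp)
  if (length(ct_number) == 0L) stop("empty calibration table", call. = FALSE)
  if (length(ct_number) != length(rsp))
    stop("ct_number and rsp lengths differ", call. = FALSE)
  if (is.unsorted(ct_number, strictly = TRUE))
    stop("ct_number must be strictly increasing", call. = FALSE)
  if (any(rsp < 0) || any(!is.finite(rsp)))
    stop("rsp must be finite and >= 0", call. = FALSE)
  i0 <- match(0, ct_number)
  if (is.na(i0) || rsp[i0] != 1)
    stop("table must contain the water anchor node (0 -> 1.0)", call. = FALSE)
  structure(data.frame(ct_number = ct_number, rsp = rsp),
            class = c("calibration_table", "data.frame"))
}

#' Default stylized CT calibration table
#'
#' A placeholder table (air, lung, water, bone-ish, dense bone); real
#' deployments should supply the scanner-specific calibration via
#' [read_calibration_table()].
#' @return a `calibration_table`.
#' @export
default_calibration_table <- function() {
  calibration_table(c(-1000, -700, 0, 1000, 2000),
                    c(0.001, 0.30, 1.0, 1.46, 2.0))
}

#' Read / write a calibration table (2-column CSV with header)
#' @param path CSV file with columns `ct_number,rsp`.
#' @return a `calibration_table`.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ct_number", "rsp") %in% names(df)))
    stop("calibration CSV needs columns ct_number,rsp", call. = FALSE)
  calibration_table(df$ct_number, df$rsp)
}

#' @rdname read_calibration_table
#' @param table a `calibration_table`.
#' @export
write_calibration_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("ct_number", "rsp")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Convert a CT-number volume to a stopping-power grid
#'
#' Per-voxel piecewise-linear interpolation of the calibration table,
#' clamped to the end nodes outside the tabulated CT range.
#'
#' @param ct_volume 3D numeric array of CT numbers, or a list with elements
#'   `data` (array), `spacing`, `origin`.
#' @param table a `calibration_table`.
#' @param spacing,origin grid geometry (used when `ct_volume` is an array).
#' @return a `voxel_grid`.
#' @export
ct_volume_to_rsp <- function(ct_volume, table = default_calibration_table(),
                             spacing = c(1, 1, 1), origin = NULL) {
  if (!inherits(table, "calibration_table"))
    stop("table must be a calibration_table", call. = FALSE)
  if (is.list(ct_volume) && !is.null(ct_volume$data)) {
    spacing <- ct_volume$spacing
    origin <- ct_volume$origin
    ct_volume <- ct_volume$data
  }
  if (any(!is.finite(ct_volume)))
    stop("CT volume must be finite", call. = FALSE)
  v <- stats::approx(table$ct_number, table$rsp, xout = as.numeric(ct_volume),
                     rule = 2)$y
  voxel_grid(array(v, dim = dim(ct_volume)), spacing, origin)
}

#' Water-equivalent path length along a straight segment
#'
#' Exact ray-voxel traversal: the sum over traversed voxels of the geometric
#' chord length inside the voxel times the voxel rsp. Voxel extents are
#' half-open `[lo, hi)`; portions of the segment outside the grid contribute
#' nothing.
#'
#' @param grid a `voxel_grid`.
#' @param start_point,end_point length-3 mm positions.
#' @return water-equivalent length in mm.
#' @export
wet_along_segment <- function(grid, start_point, end_point) {
  stopifnot(inherits(grid, "voxel_grid"))
  p0 <- as.numeric(start_point); p1 <- as.numeric(end_point)
  if (length(p0) != 3L || length(p1) != 3L || any(!is.finite(c(p0, p1))))
    stop("segment endpoints must be finite length-3 vectors", call. = FALSE)
  wet_segment_cpp(grid$rsp, dim(grid$rsp), grid$spacing, grid$origin, p0, p1)
}

#' Rectangular region mask
#'
#' Boolean mask over a grid's voxels selecting centers inside the given
#' (closed-low, open-high) mm intervals. Omitted limits span the whole axis.
#'
#' @param grid a `voxel_grid` or `dose_grid`.
#' @param xlim,ylim,zlim length-2 mm intervals or NULL.
#' @param label optional structure name (e.g. "PTV").
#' @return logical 3D array with attribute `label`.
#' @export
mask_box <- function(grid, xlim = NULL, ylim = NULL, zlim = NULL,
                     label = "region") {
  arr <- grid$rsp %||% grid$dose
  xs <- voxel_centers(grid, 1); ys <- voxel_centers(grid, 2)
  zs <- voxel_centers(grid, 3)
  inx <- if (is.null(xlim)) rep(TRUE, length(xs)) else xs >= xlim[1] & xs < xlim[2]
  iny <- if (is.null(ylim)) rep(TRUE, length(ys)) else ys >= ylim[1] & ys < ylim[2]
  inz <- if (is.null(zlim)) rep(TRUE, length(zs)) else zs >= zlim[1] & zs < zlim[2]
  m <- array(outer(outer(inx, iny, `&`), inz, `&`), dim = dim(arr))
  attr(m, "label") <- label
  m
}

#' Beam-centered comparison region
#'
#' The rectangular analysis box used for rms dose-difference reporting: full
#' width `width_mm` around the beam axis in x and y, depth 0 to `depth_mm`.
#'
#' @param grid a `voxel_grid` or `dose_grid`.
#' @param width_mm lateral full width in mm.
#' @param depth_mm depth extent in mm.
#' @return logical mask array.
#' @export
region_box <- function(grid, width_mm, depth_mm) {
  mask_box(grid, xlim = c(-width_mm / 2, width_mm / 2),
           ylim = c(-width_mm / 2, width_mm / 2),
           zlim = c(0, depth_mm), label = "analysis-box")
}
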