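#' Effective-source beam parameters
#'
#' The effective source model summarizes the beamline (including the binary
#' PMMA range shifter's scattering) as a virtual Gaussian source per
#' range-shifter setting: rms spatial spreads at the source plane, rms
#' angular spreads, and per-axis effective source-to-isocenter distances.
#' Angular spreads are stored in mrad, as tabulated.
#'
#' @param rs_thickness range-shifter thickness in mm PMMA (0-127).
#' @param sigma_x,sigma_y rms spatial spread at the source plane, mm.
#' @param sigma_tx,sigma_ty rms angular spread, mrad.
#' @param L_x,L_y effective source-to-isocenter distance, mm.
#' @return an `effective_source`.
#' @export
effective_source <- function(rs_thickness, sigma_x, sigma_y,
                             sigma_tx, sigma_ty, L_x, L_y) {
  vals <- c(sigma_x, sigma_y, sigma_tx, sigma_ty, L_x, L_y)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all source spreads and distances must be positive", call. = FALSE)
  if (rs_thickness < 0 || rs_thickness > 127)
    stop("rs_thickness must be in [0, 127] mm", call. = FALSE)
  structure(list(rs_thickness = rs_thickness,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 sigma_tx = sigma_tx, sigma_ty = sigma_ty,
                 L_x = L_x, L_y = L_y),
            class = "effective_source")
}

#' Source table: effective-source parameters vs range-shifter thickness
#'
#' @param df data.frame with columns `rs_mm, sigma_x, sigma_y, sigma_tx,
#'   sigma_ty, L_x, L_y` (angles in mrad, lengths in mm), strictly increasing
#'   `rs_mm`.
#' @return a `source_table`.
#' @export
source_table <- function(df) {
  need <- c("rs_mm", "sigma_x", "sigma_y", "sigma_tx", "sigma_ty",
            "L_x", "L_y")
  if (!all(need %in% names(df)))
    stop("source table needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (nrow(df) == 0L) stop("source table is empty", call. = FALSE)
  if (is.unsorted(df$rs_mm, strictly = TRUE))
    stop("rs_mm must be strictly increasing", call. = FALSE)
  structure(df[, need], class = c("source_table", "data.frame"))
}

#' Bundled default source table
#'
#' The four tabulated binary range-shifter settings (2, 32, 64 and 96 mm
#' PMMA) of the scanning beamline model shipped with the package.
#' @return a `source_table`.
#' @export
default_source_table <- function() {
  read_source_table(system.file("extdata", "source_table.csv",
                                package = "smcproton", mustWork = TRUE))
}

#' Read / write a source table (CSV or JSON)
#' @param path file path; `.json` is parsed with jsonlite, anything else as
#'   CSV.
#' @return a `source_table`.
#' @export
read_source_table <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else utils::read.csv(path)
  source_table(df)
}

#' @rdname read_source_table
#' @param table a `source_table`.
#' @export
write_source_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(table), path, digits = NA)
  } else utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Water-equivalent thickness of the binary range shifter
#'
#' PMMA plates with a water-equivalent thickness ratio of 1.16; thickness is
#' selectable from 0 to 127 mm in 1 mm steps.
#'
#' @param thickness_mm integer mm of PMMA in \[0, 127\].
#' @return water-equivalent thickness in mm.
#' @export
rs_wet <- function(thickness_mm) {
  t <- as.numeric(thickness_mm)
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > 127 ||
      abs(t - round(t)) > 1e-9)
    stop("range-shifter thickness must be an integer in [0, 127] mm",
         call. = FALSE)
  t * 1.16
}

#' Look up (or interpolate) effective-source parameters
#'
#' Exact tabulated entry when `rs_mm` is in the table, otherwise field-wise
#' linear interpolation between the bracketing entries. No extrapolation:
#' settings outside the tabulated span raise an error.
#'
#' @param table a `source_table`.
#' @param rs_mm range-shifter thickness in mm.
#' @return an `effective_source`.
#' @export
lookup_source <- function(table, rs_mm) {
  stopifnot(inherits(table, "source_table"))
  rs <- table$rs_mm
  if (rs_mm < min(rs) || rs_mm > max(rs))
    stop(sprintf("rs = %g mm outside the tabulated span [%g, %g]",
                 rs_mm, min(rs), max(rs)), call. = FALSE)
  interp <- function(col) stats::approx(rs, table[[col]], xout = rs_mm)$y
  effective_source(rs_mm,
                   sigma_x = interp("sigma_x"), sigma_y = interp("sigma_y"),
                   sigma_tx = interp("sigma_tx"), sigma_ty = interp("sigma_ty"),
                   L_x = interp("L_x"), L_y = interp("L_y"))
}

#' Pencil-beam spot
#'
#' @param x_iso,y_iso lateral spot position at the isocenter plane, mm.
#' @param energy nominal beam energy in MeV.
#' @param rs_thickness binary range-shifter setting, integer mm in \[0, 127\].
#' @param layer_wed intended Bragg-peak water-equivalent depth, mm (optional
#'   bookkeeping).
#' @param weight spot weight (protons, arbitrary scale).
#' @return a `spot`.
#' @export
spot <- function(x_iso, y_iso, energy = 206, rs_thickness = 2,
                 layer_wed = NA_real_, weight = 1) {
  if (energy <= 0) stop("energy must be positive", call. = FALSE)
  if (rs_thickness < 0 || rs_thickness > 127 ||
      abs(rs_thickness - round(rs_thickness)) > 1e-9)
    stop("rs_thickness must be an integer in [0, 127]", call. = FALSE)
  structure(list(x_iso = x_iso, y_iso = y_iso, energy = energy,
                 rs_thickness = as.integer(round(rs_thickness)),
                 layer_wed = layer_wed, weight = weight),
            class = "spot")
}

#' Read / write spot lists as JSON
#' @param path JSON file of objects with fields x_iso, y_iso, energy,
#'   rs_thickness, weight (and optionally layer_wed).
#' @return list of `spot` objects.
#' @export
read_spots <- function(path) {
  df <- jsonlite::fromJSON(path)
  lapply(seq_len(nrow(df)), function(i)
    spot(df$x_iso[i], df$y_iso[i], df$energy[i], df$rs_thickness[i],
         if ("layer_wed" %in% names(df)) df$layer_wed[i] else NA_real_,
         if ("weight" %in% names(df)) df$weight[i] else 1))
}

#' @rdname read_spots
#' @param spots list of `spot` objects.
#' @export
write_spots <- function(spots, path) {
  df <- do.call(rbind, lapply(spots, function(s)
    data.frame(x_iso = s$x_iso, y_iso = s$y_iso, energy = s$energy,
               rs_thickness = s$rs_thickness, layer_wed = s$layer_wed,
               weight = s$weight)))
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' Derive a per-spot seed from a base seed
#'
#' Keeps plans reproducible spot-by-spot while staying inside R's 32-bit
#' integer range.
#' @param base_seed integer base seed.
#' @param index spot index (1-based).
#' @return integer seed.
#' @export
spot_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) + 1000003 * as.numeric(index)) %%
               2147483629)
}

#' Sample the initial proton ensemble of a spot
#'
#' Positions at the effective source plane are Gaussian (sigma_x/sigma_y)
#' about the spot's aiming ray — a parallel-shifted ray through
#' (x_iso, y_iso) along +z — and projection angles are independent Gaussians
#' (sigma_tx/sigma_ty in mrad) about that ray's direction. Each axis has its
#' own source plane at z = iso_z - L (per-axis effective distances); protons
#' are then drifted ballistically (vacuum, no scattering) to the entrance
#' plane `entrance_z`. With `entrance_z = NULL` no drift is applied and the
#' returned x/y are the source-plane coordinates.
#'
#' @param source an `effective_source`.
#' @param spot a `spot`.
#' @param n number of protons (>= 0).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   identical inputs give bit-identical ensembles.
#' @param entrance_z z of the phantom entrance plane in mm (default 0), or
#'   NULL for source-plane coordinates.
#' @param iso_z z of the isocenter plane in mm (default 0: isocenter at the
#'   entrance face).
#' @return a `proton_ensemble` data.frame with columns x, y, z, tx, ty
#'   (rad) and residual_range (mm water; NA until the engine assigns it).
#' @export
sample_spot_protons <- function(source, spot, n, seed = NULL,
                                entrance_z = 0, iso_z = 0) {
  stopifnot(inherits(source, "effective_source"), inherits(spot, "spot"))
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, spot$x_iso, source$sigma_x)
  y <- stats::rnorm(n, spot$y_iso, source$sigma_y)
  tx <- stats::rnorm(n, 0, source$sigma_tx * 1e-3)
  ty <- stats::rnorm(n, 0, source$sigma_ty * 1e-3)
  z <- rep(if (is.null(entrance_z)) iso_z - source$L_x else entrance_z, n)
  if (!is.null(entrance_z)) {
    dx <- entrance_z - (iso_z - source$L_x)
    dy <- entrance_z - (iso_z - source$L_y)
    if (dx < 0 || dy < 0)
      stop("entrance plane must be downstream of the source planes",
           call. = FALSE)
    x <- x + tx * dx
    y <- y + ty * dy
  }
  structure(data.frame(x = x, y = y, z = z, tx = tx, ty = ty,
                       residual_range = rep(NA_real_, n)),
            class = c("proton_ensemble", "data.frame"))
}
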