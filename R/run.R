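#' Benchmark run configuration
#'
#' @param n_protons protons for the SMC kernel (default 1e5; use 1e6 for
#'   full-fidelity runs).
#' @param seed integer RNG seed.
#' @param bone_rsp,lung_rsp slab stopping powers.
#' @param peak_depth_mm water Bragg-peak depth of the pristine curve.
#' @param rs_thickness range-shifter setting, mm PMMA.
#' @param energy nominal beam energy, MeV.
#' @param with_pba also compute the analytical kernel and a difference
#'   report.
#' @param out_dir output directory (created), or NULL for no file output.
#' @return a `run_config` list.
#' @export
benchmark_config <- function(n_protons = 1e5, seed = 1L, bone_rsp = 1.46,
                             lung_rsp = 0.217, peak_depth_mm = 257.5,
                             rs_thickness = 2, energy = 206,
                             with_pba = FALSE, out_dir = NULL) {
  if (n_protons < 1) stop("n_protons must be >= 1", call. = FALSE)
  structure(list(n_protons = as.integer(n_protons), seed = as.integer(seed),
                 bone_rsp = bone_rsp, lung_rsp = lung_rsp,
                 peak_depth_mm = peak_depth_mm,
                 rs_thickness = rs_thickness, energy = energy,
                 with_pba = isTRUE(with_pba), out_dir = out_dir),
            class = "run_config")
}

#' Run the heterogeneity benchmark
#'
#' Builds the bone/lung benchmark phantom, transports an on-axis pencil beam
#' with the SMC engine, and reports the laterally integrated depth dose and
#' its Bragg-peak table (the bone-path, water-path and lung-path peaks).
#' Optionally also computes the analytical PBA kernel and an isodose
#' difference report. When `out_dir` is set, writes `lidd.csv`, `peaks.csv`,
#' a `manifest.json` sufficient to reproduce the run bit-identically, and
#' (with PBA) the isodose report files.
#'
#' @param config a [benchmark_config()].
#' @return list with `lidd` (data.frame), `peaks` (data.frame), `kernel`
#'   (SMC `dose_kernel`), `pba` (or NULL), `files`.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "run_config"))
  ph <- make_benchmark_phantom(config$bone_rsp, config$lung_rsp)
  curve <- make_bragg_curve(config$peak_depth_mm)
  stab <- default_source_table()
  sp <- spot(0, 0, energy = config$energy,
             rs_thickness = config$rs_thickness)
  # the benchmark curve is calibrated to its in-water peak depth behind the
  # range shifter, so no additional upstream water-equivalent offset applies
  kern <- compute_kernel(sp, ph$grid, curve, stab, config$n_protons,
                         seed = config$seed, rs_in_curve = TRUE)
  lidd <- laterally_integrated_depth_dose(kern)
  peaks <- find_peaks(lidd$z, lidd$dose)
  pba <- NULL
  files <- character()
  if (config$with_pba)
    pba <- pba_kernel(sp, ph$grid, curve, stab, rs_in_curve = TRUE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f_lidd <- file.path(config$out_dir, "lidd.csv")
    f_peaks <- file.path(config$out_dir, "peaks.csv")
    f_manifest <- file.path(config$out_dir, "manifest.json")
    utils::write.csv(lidd, f_lidd, row.names = FALSE)
    utils::write.csv(peaks, f_peaks, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config),
           package_version = as.character(utils::packageVersion("smcproton"))),
      f_manifest, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(lidd = f_lidd, peaks = f_peaks, manifest = f_manifest)
    if (config$with_pba) {
      rep_files <- export_isodose_report(
        kern, pba, path_prefix = file.path(config$out_dir, "isodose"))
      files <- c(files, rep_files)
    }
  }
  list(lidd = lidd, peaks = peaks, kernel = kern, pba = pba, files = files)
}

#' SFUD plan run configuration
#'
#' @param phantom a `voxel_grid`.
#' @param ptv_mask logical array over the phantom.
#' @param curve a `depth_dose_curve`.
#' @param source_table a `source_table`.
#' @param prescription target dose per voxel (kernel units x weight).
#' @param n_protons protons per SMC kernel.
#' @param seed base seed.
#' @param lateral_spacing_mm,layer_spacing_wed_mm,margin_mm spot-grid
#'   parameters (see [generate_spot_grid()]).
#' @param oar_mask optional organ-at-risk mask (DVH reporting only by
#'   default).
#' @param out_dir optional output directory.
#' @return a `plan_config`.
#' @export
plan_config <- function(phantom, ptv_mask, curve,
                        source_table = default_source_table(),
                        prescription = 1, n_protons = 2e4, seed = 1L,
                        lateral_spacing_mm = 12, layer_spacing_wed_mm = 5,
                        margin_mm = 12, oar_mask = NULL, out_dir = NULL) {
  structure(list(phantom = phantom, ptv_mask = ptv_mask, curve = curve,
                 source_table = source_table, prescription = prescription,
                 n_protons = as.integer(n_protons), seed = as.integer(seed),
                 lateral_spacing_mm = lateral_spacing_mm,
                 layer_spacing_wed_mm = layer_spacing_wed_mm,
                 margin_mm = margin_mm, oar_mask = oar_mask,
                 out_dir = out_dir),
            class = "plan_config")
}

#' Run the three-way SFUD planning comparison
#'
#' Generates the spot grid over the PTV, computes kernel matrices with both
#' engines, optimizes spot weights against each, and assembles the three
#' dose results the planning comparison rests on:
#' \describe{
#'   \item{pba_tp}{PBA kernels with PBA-optimized weights — what the
#'     analytical planning system believes it delivers.}
#'   \item{smc_recalc}{SMC kernels with the PBA-optimized weights — what
#'     that plan actually delivers according to the Monte Carlo engine.}
#'   \item{smc_tp}{SMC kernels with SMC-optimized weights — planning on the
#'     Monte Carlo kernels directly.}
#' }
#' DVHs and D95/D5 are reported per structure; outputs are written under
#' `out_dir` when set (plan JSONs, DVH CSVs, manifest).
#'
#' @param config a [plan_config()].
#' @return list with `spots`, `weights` (pba/smc), per-arm masked doses,
#'   `dvhs`, `metrics` (data.frame of D95/D5 per arm) and `files`.
#' @export
run_plan <- function(config) {
  stopifnot(inherits(config, "plan_config"))
  grid <- config$phantom
  masks <- list(PTV = config$ptv_mask)
  if (!is.null(config$oar_mask)) masks$OAR <- config$oar_mask
  spots <- generate_spot_grid(config$ptv_mask, grid, config$curve,
                              config$lateral_spacing_mm,
                              config$layer_spacing_wed_mm, config$margin_mm,
                              rs_range = range(config$source_table$rs_mm))
  km_smc <- compute_kernel_matrix(spots, grid, config$curve,
                                  config$source_table, masks,
                                  engine = "smc", n = config$n_protons,
                                  seed = config$seed)
  km_pba <- compute_kernel_matrix(spots, grid, config$curve,
                                  config$source_table, masks,
                                  engine = "pba")
  w_pba <- optimize_weights(km_pba, prescription = config$prescription)
  w_smc <- optimize_weights(km_smc, prescription = config$prescription)
  doses <- list(pba_tp = total_dose(km_pba, w_pba),
                smc_recalc = total_dose(km_smc, w_pba),
                smc_tp = total_dose(km_smc, w_smc))
  ptv_rows <- km_smc$masks$PTV
  metrics <- do.call(rbind, lapply(names(doses), function(nm) {
    v <- doses[[nm]][ptv_rows]
    dv <- dvh(array(v), array(TRUE, dim = length(v)), config$prescription)
    data.frame(arm = nm, d95 = d_at_volume(dv, 95), d5 = d_at_volume(dv, 5))
  }))
  metrics$spread <- metrics$d5 - metrics$d95
  dvhs <- lapply(names(doses), function(nm) {
    out <- lapply(names(masks), function(mn) {
      rows <- km_smc$masks[[mn]]
      v <- doses[[nm]][rows]
      dvh(array(v), array(TRUE, dim = length(v)), config$prescription)
    })
    names(out) <- names(masks)
    out
  })
  names(dvhs) <- names(doses)

  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("pba", "smc")) {
      w <- if (nm == "pba") w_pba else w_smc
      f <- file.path(config$out_dir, paste0("plan_", nm, ".json"))
      write_plan(list(field_id = paste0(nm, "_tp"), spots = spots,
                      weights = as.numeric(w),
                      prescription = config$prescription), f)
      files <- c(files, stats::setNames(f, paste0("plan_", nm)))
    }
    for (nm in names(dvhs)) {
      f <- file.path(config$out_dir, paste0("dvh_", nm, "_PTV.csv"))
      utils::write.csv(dvhs[[nm]]$PTV, f, row.names = FALSE)
      files <- c(files, stats::setNames(f, paste0("dvh_", nm)))
    }
    f_metrics <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(metrics, f_metrics, row.names = FALSE)
    f_manifest <- file.path(config$out_dir, "manifest.json")
    cfg <- config[c("prescription", "n_protons", "seed",
                    "lateral_spacing_mm", "layer_spacing_wed_mm",
                    "margin_mm")]
    jsonlite::write_json(
      list(config = cfg, n_spots = length(spots),
           package_version = as.character(utils::packageVersion("smcproton"))),
      f_manifest, auto_unbox = TRUE, digits = NA)
    files <- c(files, metrics = f_metrics, manifest = f_manifest)
  }
  list(spots = spots, weights = list(pba = w_pba, smc = w_smc),
       doses = doses, dvhs = dvhs, metrics = metrics,
       kernel_matrices = list(smc = km_smc, pba = km_pba), files = files)
}
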