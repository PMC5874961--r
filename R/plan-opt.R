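#' Generate a SFUD spot grid over a target mask
#'
#' Lateral spot positions on a regular lattice (default 12 mm pitch) covering
#' the target's beam's-eye-view footprint plus margin, anchored at the
#' footprint minimum corner; energy layers at water-equivalent depths
#' (default 5 mm apart) spanning the target's WED extent. Each layer is
#' realized with the binary range shifter: a layer at WED d gets
#' rs = round((peak_wed - d) / 1.16) mm of PMMA, clamped to `rs_range`, so a
#' single pristine curve serves all layers.
#'
#' @param ptv_mask logical array over `grid` (non-empty).
#' @param grid a `voxel_grid`.
#' @param curve a `depth_dose_curve` (defines the deepest reachable layer).
#' @param lateral_spacing_mm lattice pitch in x and y, mm.
#' @param layer_spacing_wed_mm layer separation in water-equivalent depth, mm.
#' @param margin_mm lateral margin added around the footprint, mm.
#' @param energy nominal beam energy recorded on the spots, MeV.
#' @param rs_range admissible range-shifter settings (clamped; keep inside
#'   the source table's span).
#' @return list of `spot` objects (with `layer_wed` set).
#' @export
generate_spot_grid <- function(ptv_mask, grid, curve,
                               lateral_spacing_mm = 12,
                               layer_spacing_wed_mm = 5, margin_mm = 0,
                               energy = 206, rs_range = c(0, 127)) {
  if (!any(ptv_mask)) stop("empty PTV mask", call. = FALSE)
  if (lateral_spacing_mm <= 0 || layer_spacing_wed_mm <= 0)
    stop("spacings must be positive", call. = FALSE)
  idx <- which(ptv_mask, arr.ind = TRUE)
  xs <- voxel_centers(grid, 1)[idx[, 1]]
  ys <- voxel_centers(grid, 2)[idx[, 2]]
  lat_x <- seq(min(xs) - margin_mm, max(xs) + margin_mm,
               by = lateral_spacing_mm)
  lat_y <- seq(min(ys) - margin_mm, max(ys) + margin_mm,
               by = lateral_spacing_mm)

  # WED of each PTV voxel center along its own column
  dz <- grid$spacing[3]
  cols <- unique(idx[, 1:2, drop = FALSE])
  wed <- numeric(nrow(idx))
  for (r in seq_len(nrow(cols))) {
    i <- cols[r, 1]; j <- cols[r, 2]
    cum <- cumsum(grid$rsp[i, j, ] * dz)
    sel <- idx[, 1] == i & idx[, 2] == j
    kz <- idx[sel, 3]
    wed[sel] <- cum[kz] - grid$rsp[i, j, kz] * dz / 2
  }
  layers <- seq(min(wed), max(wed), by = layer_spacing_wed_mm)
  if (max(layers) < max(wed)) layers <- c(layers, max(wed))

  peak <- curve_peak_depth(curve)
  spots <- list()
  for (lw in layers) {
    rs <- round((peak - lw) / 1.16)
    rs <- min(max(rs, rs_range[1], 0), rs_range[2], 127)
    for (px in lat_x) for (py in lat_y)
      spots[[length(spots) + 1L]] <-
        spot(px, py, energy = energy, rs_thickness = rs, layer_wed = lw)
  }
  spots
}

#' Kernel matrix over the voxels of interest
#'
#' Restriction of a set of dose kernels to the union of the structure masks:
#' rows are the sorted linear voxel indices of the union, column j is kernel
#' j's per-proton dose on those voxels. This is the optimizer's system
#' matrix.
#'
#' @param kernels list of `dose_kernel` (sharing one grid geometry).
#' @param masks logical array or named list of logical arrays.
#' @return a `kernel_matrix`: list with `A` (dense matrix), `rows` (linear
#'   voxel indices), `masks` (row-index sets per structure), `spots`.
#' @export
assemble_kernel_matrix <- function(kernels, masks) {
  if (!is.list(masks) || is.array(masks)) masks <- list(region = masks)
  dims <- lapply(kernels, function(k) dim(k$dose))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    stop("kernels are on different grids", call. = FALSE)
  union <- Reduce(`|`, masks)
  rows <- which(union)
  A <- vapply(kernels, function(k) k$dose[rows], numeric(length(rows)))
  A <- matrix(A, nrow = length(rows))
  row_sets <- lapply(masks, function(m) match(which(m), rows))
  structure(list(A = A, rows = rows,
                 masks = lapply(row_sets, function(s) s[!is.na(s)]),
                 spots = lapply(kernels, function(k) k$spot)),
            class = "kernel_matrix")
}

#' Stream a kernel matrix without storing full kernels
#'
#' Computes each spot's kernel (SMC or PBA), keeps only the masked voxels,
#' and discards the full volume — memory stays proportional to the voxels of
#' interest, as required for realistic spot counts.
#'
#' @param spots list of `spot`.
#' @param grid,curve,source_table,scattering as in [compute_kernel()].
#' @param masks logical array or named list of arrays.
#' @param engine "smc" or "pba".
#' @param n protons per SMC kernel.
#' @param seed base seed; spot j uses `spot_seed(seed, j)`.
#' @param config `pba_config` for the PBA engine.
#' @return a `kernel_matrix`.
#' @export
compute_kernel_matrix <- function(spots, grid, curve, source_table, masks,
                                  engine = c("smc", "pba"), n = 1e4,
                                  seed = 1L, config = pba_config(),
                                  scattering = scattering_model()) {
  engine <- match.arg(engine)
  if (!is.list(masks) || is.array(masks)) masks <- list(region = masks)
  union <- Reduce(`|`, masks)
  rows <- which(union)
  A <- matrix(0, nrow = length(rows), ncol = length(spots))
  for (j in seq_along(spots)) {
    kj <- if (engine == "smc") {
      compute_kernel(spots[[j]], grid, curve, source_table, n,
                     seed = spot_seed(seed, j), scattering = scattering)
    } else {
      pba_kernel(spots[[j]], grid, curve, source_table, config = config,
                 scattering = scattering)
    }
    A[, j] <- kj$dose[rows]
  }
  row_sets <- lapply(masks, function(m) match(which(m), rows))
  structure(list(A = A, rows = rows,
                 masks = lapply(row_sets, function(s) s[!is.na(s)]),
                 spots = spots),
            class = "kernel_matrix")
}

#' Nonnegative spot-weight optimization (SFUD objective)
#'
#' Minimizes
#' `sum_PTV (D_i - P)^2 + sum_OAR lambda * max(0, D_i - cap)^2 + reg * sum w^2`
#' subject to `w >= 0`, with `D = A w`, by projected gradient descent with a
#' monotone backtracking line search (the objective never increases across
#' iterations). Start: uniform weights scaled so the mean PTV dose equals the
#' prescription.
#'
#' @param kmat a `kernel_matrix`, or a plain dose matrix.
#' @param ptv_rows row indices of the PTV (default: the mask named "PTV" or
#'   the first mask of `kmat`).
#' @param prescription target dose P (> 0), in the kernels' dose units.
#' @param oar_terms list of lists with `rows`, `cap`, `lambda`: one-sided
#'   overdose penalties (defaults off).
#' @param reg Tikhonov weight on `sum w^2`.
#' @param max_iter,tol iteration cap and relative objective tolerance.
#' @return non-negative weight vector with attributes `objective` (final
#'   value) and `history` (per-iteration objective, non-increasing).
#' @export
optimize_weights <- function(kmat, ptv_rows = NULL, prescription,
                             oar_terms = NULL, reg = 0,
                             max_iter = 5000, tol = 1e-6) {
  A <- if (inherits(kmat, "kernel_matrix")) kmat$A else as.matrix(kmat)
  if (is.null(ptv_rows)) {
    if (!inherits(kmat, "kernel_matrix"))
      stop("ptv_rows required for a plain matrix", call. = FALSE)
    nm <- names(kmat$masks)
    pick <- if ("PTV" %in% nm) "PTV" else 1L
    ptv_rows <- kmat$masks[[pick]]
  }
  if (!length(A) || nrow(A) == 0L || ncol(A) == 0L)
    stop("empty kernel matrix", call. = FALSE)
  if (prescription <= 0) stop("prescription must be positive", call. = FALSE)
  Ap <- A[ptv_rows, , drop = FALSE]
  if (all(Ap == 0)) stop("degenerate problem: PTV receives no dose",
                         call. = FALSE)

  objective <- function(w) {
    dp <- Ap %*% w - prescription
    val <- sum(dp^2) + reg * sum(w^2)
    for (ot in oar_terms) {
      ex <- pmax(A[ot$rows, , drop = FALSE] %*% w - ot$cap, 0)
      val <- val + ot$lambda * sum(ex^2)
    }
    val
  }
  gradient <- function(w) {
    g <- 2 * crossprod(Ap, Ap %*% w - prescription) + 2 * reg * w
    for (ot in oar_terms) {
      Ao <- A[ot$rows, , drop = FALSE]
      ex <- pmax(Ao %*% w - ot$cap, 0)
      g <- g + 2 * ot$lambda * crossprod(Ao, ex)
    }
    as.numeric(g)
  }

  # Lipschitz constant of the gradient: power iteration on the PTV normal
  # matrix, plus upper bounds for the (one-sided) OAR terms and the ridge
  pow_norm <- function(M) {
    v <- rep(1, ncol(M))
    nv <- 1
    for (i in 1:60) {
      v <- crossprod(M, M %*% v)
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(0)
      v <- v / nv
    }
    nv
  }
  L <- 2 * pow_norm(Ap) + 2 * reg
  for (ot in oar_terms) L <- L + 2 * ot$lambda * pow_norm(A[ot$rows, , drop = FALSE])
  L <- max(L, .Machine$double.eps)

  mean_unit <- mean(Ap %*% rep(1, ncol(A)))
  w <- rep(if (mean_unit > 0) prescription / mean_unit else 0, ncol(A))
  f <- objective(w)
  history <- f
  # monotone FISTA: accelerated proximal-gradient step, falling back to a
  # plain projected-gradient step whenever acceleration would overshoot, so
  # the recorded objective never increases
  v <- w
  tk <- 1
  stall <- 0L
  for (it in seq_len(max_iter)) {
    z <- pmax(v - gradient(v) / L, 0)
    f_z <- objective(z)
    if (f_z > f) {
      z <- pmax(w - gradient(w) / L, 0)
      f_z <- objective(z)
      if (f_z > f) { z <- w; f_z <- f }
      tk <- 1  # restart momentum
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- z + ((tk - 1) / t_next) * (z - w)
    stall <- if ((f - f_z) <= tol * max(f, .Machine$double.eps))
      stall + 1L else 0L
    w <- z; f <- f_z; tk <- t_next
    history <- c(history, f)
    if (stall >= 10L) break
  }
  structure(w, objective = f, history = history,
            iterations = length(history) - 1L)
}

#' Superpose weighted dose kernels
#'
#' `sum_j w_j * kernel_j`, the treatment dose of a plan. Supports
#' cross-engine recalculation: weights optimized against one engine's
#' kernels applied to the other engine's kernels.
#'
#' @param kernels list of `dose_kernel` on one grid, or a `kernel_matrix`.
#' @param weights numeric vector, `length(weights) == length(kernels)`.
#' @return a `dose_grid` (or, for a `kernel_matrix`, a numeric vector of
#'   doses on the matrix rows).
#' @export
total_dose <- function(kernels, weights) {
  if (inherits(kernels, "kernel_matrix")) {
    if (length(weights) != ncol(kernels$A))
      stop("weights length must match the number of spots", call. = FALSE)
    return(as.numeric(kernels$A %*% weights))
  }
  if (length(kernels) != length(weights))
    stop("kernels and weights lengths differ", call. = FALSE)
  if (!length(kernels)) stop("no kernels", call. = FALSE)
  acc <- array(0, dim = dim(kernels[[1]]$dose))
  for (j in seq_along(kernels)) acc <- acc + weights[j] * kernels[[j]]$dose
  dose_grid(acc, kernels[[1]]$spacing, kernels[[1]]$origin)
}

#' Read / write a plan (spots + weights + prescription) as JSON
#' @param plan list with `spots`, `weights`, `prescription`, `field_id`.
#' @param path JSON path.
#' @return the plan list (read) or `path` invisibly (write).
#' @export
write_plan <- function(plan, path) {
  df <- do.call(rbind, lapply(plan$spots, function(s)
    data.frame(x_iso = s$x_iso, y_iso = s$y_iso, energy = s$energy,
               rs_thickness = s$rs_thickness, layer_wed = s$layer_wed)))
  jsonlite::write_json(list(field_id = plan$field_id,
                            prescription = plan$prescription,
                            spots = df, weights = plan$weights),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  p <- jsonlite::fromJSON(path)
  spots <- lapply(seq_len(nrow(p$spots)), function(i)
    spot(p$spots$x_iso[i], p$spots$y_iso[i], p$spots$energy[i],
         p$spots$rs_thickness[i], p$spots$layer_wed[i]))
  list(field_id = p$field_id, prescription = p$prescription,
       spots = spots, weights = p$weights)
}
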