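# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

# Exact WET along a segment by enumerating every boundary-crossing parameter
# and integrating rsp at sub-segment midpoints.
oracle_wet <- function(grid, p0, p1) {
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(0)
  d <- dim(grid$rsp)
  edges <- lapply(1:3, function(a)
    grid$origin[a] - grid$spacing[a] / 2 + (0:d[a]) * grid$spacing[a])
  ts <- c(0, 1)
  for (a in 1:3) {
    u <- p1[a] - p0[a]
    if (u != 0) ts <- c(ts, (edges[[a]] - p0[a]) / u)
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  wet <- 0
  for (i in seq_len(length(ts) - 1)) {
    tm <- (ts[i] + ts[i + 1]) / 2
    pm <- p0 + tm * (p1 - p0)
    iv <- floor((pm - (grid$origin - grid$spacing / 2)) / grid$spacing) + 1
    if (all(iv >= 1) && all(iv <= d))
      wet <- wet + (ts[i + 1] - ts[i]) * L * grid$rsp[iv[1], iv[2], iv[3]]
  }
  wet
}

# Global NNLS optimum by exhaustive active-set enumeration (tiny systems):
# for each support set solve the unconstrained least squares and keep the
# best feasible solution.
oracle_nnls <- function(A, b, reg = 0) {
  p <- ncol(A)
  best <- rep(0, p)
  bestf <- sum(b^2)
  for (S in seq_len(2^p) - 1L) {
    act <- which(bitwAnd(S, 2^(seq_len(p) - 1)) > 0)
    if (!length(act)) next
    As <- A[, act, drop = FALSE]
    M <- crossprod(As) + reg * diag(length(act))
    sol <- tryCatch(solve(M, crossprod(As, b)), error = function(e) NULL)
    if (is.null(sol) || any(sol < 0)) next
    w <- rep(0, p)
    w[act] <- sol
    f <- sum((A %*% w - b)^2) + reg * sum(w^2)
    if (f < bestf) { bestf <- f; best <- w }
  }
  list(w = best, objective = bestf)
}

# Straight R re-implementation of the global-normalization gamma search on a
# small grid (trilinear interpolation restricted to the voxel-center box).
oracle_gamma <- function(ref, ev, spacing, origin, dta, dd_abs, cutoff_abs,
                         search_mm, sub_mm) {
  d <- dim(ref)
  interp <- function(p) {
    f <- (p - origin) / spacing
    if (any(f < 0) || any(f > d - 1)) return(NA_real_)
    i <- pmin(floor(f), d - 2)
    w <- f - i
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wt <- (if (a) w[1] else 1 - w[1]) * (if (b) w[2] else 1 - w[2]) *
        (if (cc) w[3] else 1 - w[3])
      acc <- acc + wt * ref[i[1] + 1 + a, i[2] + 1 + b, i[3] + 1 + cc]
    }
    acc
  }
  m <- floor(search_mm / sub_mm)
  offs <- expand.grid(ox = (-m:m) * sub_mm, oy = (-m:m) * sub_mm,
                      oz = (-m:m) * sub_mm)
  g <- array(NA_real_, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (ref[i, j, k] < cutoff_abs) next
    p <- origin + (c(i, j, k) - 1) * spacing
    de <- ev[i, j, k]
    best <- Inf
    for (r in seq_len(nrow(offs))) {
      o <- as.numeric(offs[r, ])
      dr <- interp(p + o)
      if (is.na(dr)) next
      g2 <- sum(o^2) / dta^2 + (de - dr)^2 / dd_abs^2
      if (g2 < best) best <- g2
    }
    g[i, j, k] <- sqrt(best)
  }
  g
}

# Deterministic "random" dose arrays for metric oracle tests
random_dose_array <- function(dims, seed) {
  set.seed(seed)
  array(stats::runif(prod(dims)), dim = dims)
}

# energy-weighted lateral standard deviation of a dose slice at one depth
lateral_sd <- function(dose, xs, iz) {
  prof <- rowSums(dose[, , iz])
  m <- sum(prof * xs) / sum(prof)
  sqrt(sum(prof * (xs - m)^2) / sum(prof))
}
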