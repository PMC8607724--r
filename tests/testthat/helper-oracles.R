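# Independent oracles and fixture builders shared across the test files.

# A detector small enough to fit inside compact test grids.
small_geometry <- function() detector_geometry(10, 8, 5, 40)

# --- brute-force gamma oracle -------------------------------------------
# Independent of the engine: its own bilinear interpolation, a dense lattice
# at half the engine's coarse step (restricted only by the provably exact
# bound radius = dta * gamma0), and Nelder-Mead polishing from the lattice
# minimum.

oracle_bilinear <- function(grid, y, x) {
  v <- grid$values; sp <- grid$spacing_mm; og <- grid$origin_mm
  ny <- nrow(v); nx <- ncol(v)
  gy <- (y - og[1]) / sp[1]; gx <- (x - og[2]) / sp[2]
  out <- rep(NA_real_, length(y))
  ok <- gy >= 0 & gy <= ny - 1 & gx >= 0 & gx <= nx - 1
  iy <- pmin(floor(gy[ok]), ny - 2); ix <- pmin(floor(gx[ok]), nx - 2)
  ty <- gy[ok] - iy; tx <- gx[ok] - ix
  get <- function(dy, dx) v[cbind(iy + 1 + dy, ix + 1 + dx)]
  out[ok] <- (1 - ty) * (1 - tx) * get(0, 0) + (1 - ty) * tx * get(0, 1) +
    ty * (1 - tx) * get(1, 0) + ty * tx * get(1, 1)
  out
}

brute_gamma <- function(reference, evaluation, criteria) {
  pts <- reference$points
  d_norm <- max(evaluation$values)
  ext <- rbind(evaluation$origin_mm,
               evaluation$origin_mm + (dim(evaluation$values) - 1) * evaluation$spacing_mm)
  dta <- criteria$dta_mm
  step <- criteria$interp_step_mm / 2
  delta_d <- if (criteria$normalization == "global") {
    rep(criteria$dd_percent / 100 * d_norm, nrow(pts))
  } else {
    criteria$dd_percent / 100 * pts$dose_Gy
  }
  vapply(seq_len(nrow(pts)), function(i) {
    y0 <- pts$v_mm[i]; x0 <- pts$u_mm[i]; dr <- pts$dose_Gy[i]
    if (delta_d[i] <= 0) return(Inf)
    g2 <- function(y, x) {
      de <- oracle_bilinear(evaluation, y, x)
      ((y - y0)^2 + (x - x0)^2) / dta^2 + ((de - dr) / delta_d[i])^2
    }
    g0 <- sqrt(g2(y0, x0))
    if (g0 == 0) return(0)
    # candidates farther than dta * gamma0 lose on the distance term alone
    radius <- dta * g0 + step
    off <- seq(-ceiling(radius / step), ceiling(radius / step)) * step
    yy <- pmin(pmax(y0 + rep(off, times = length(off)), ext[1, 1]), ext[2, 1])
    xx <- pmin(pmax(x0 + rep(off, each = length(off)), ext[1, 2]), ext[2, 2])
    vals <- g2(yy, xx)
    obj <- function(p) g2(min(max(p[1], ext[1, 1]), ext[2, 1]),
                          min(max(p[2], ext[1, 2]), ext[2, 2]))
    # polish from several distinct lattice candidates; restart Nelder-Mead
    # once from each converged point (a fresh simplex escapes stalls on the
    # kinked piecewise-bilinear surface)
    ord <- order(vals)
    starts <- list(c(yy[ord[1]], xx[ord[1]]))
    for (j in ord[-1]) {
      if (length(starts) >= 4) break
      if (all(vapply(starts, function(s0)
        sum((s0 - c(yy[j], xx[j]))^2), 1.0) > (2 * step)^2)) {
        starts <- c(starts, list(c(yy[j], xx[j])))
      }
    }
    best <- vals[ord[1]]
    for (s0 in starts) {
      p1 <- stats::optim(s0, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 4000))
      p2 <- stats::optim(p1$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 4000))
      best <- min(best, p1$value, p2$value)
    }
    sqrt(best)
  }, 1.0)
}

# Mean of min(X, upper) for X ~ Normal(mean, sd): the realized-mean oracle
# for passing rates clipped at 100.
clipnorm_mean <- function(mean, sd, upper = 100) {
  beta <- (upper - mean) / sd
  upper - (upper - mean) * stats::pnorm(beta) - sd * stats::dnorm(beta)
}

# --- hand-built DICOM RT Dose fixture -----------------------------------
# Byte-level construction, independent of the package writer: explicit VR
# little endian, 2 x 2 single-frame dose grid with stored 32-bit ints.

dicom_fixture_bytes <- function(stored_ints = c(1000L, 2000L, 3000L, 4000L),
                                scaling = 0.001, modality = "RTDOSE",
                                spacing = c(1.5, 2.5), ipp = c(10, 20, 0)) {
  u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  pad <- function(r, ui = FALSE) {
    if (length(r) %% 2 == 1) c(r, if (ui) as.raw(0) else charToRaw(" ")) else r
  }
  short_el <- function(g, e, vr, val) {
    val <- pad(val, ui = vr == "UI")
    c(u16r(g), u16r(e), charToRaw(vr), u16r(length(val)), val)
  }
  long_el <- function(g, e, vr, val) {
    val <- pad(val)
    c(u16r(g), u16r(e), charToRaw(vr), as.raw(c(0, 0)), u32r(length(val)), val)
  }
  ts <- charToRaw("1.2.840.10008.1.2.1")
  meta <- short_el(0x0002, 0x0010, "UI", ts)
  meta_len <- short_el(0x0002, 0x0000, "UL", u32r(length(meta)))
  body <- c(
    short_el(0x0008, 0x0060, "CS", charToRaw(modality)),
    short_el(0x0020, 0x0032, "DS",
             charToRaw(paste(sprintf("%g", ipp), collapse = "\\"))),
    short_el(0x0028, 0x0008, "IS", charToRaw("1")),
    short_el(0x0028, 0x0010, "US", u16r(2)),
    short_el(0x0028, 0x0011, "US", u16r(2)),
    short_el(0x0028, 0x0030, "DS",
             charToRaw(paste(sprintf("%g", spacing), collapse = "\\"))),
    short_el(0x0028, 0x0100, "US", u16r(32)),
    short_el(0x3004, 0x0002, "CS", charToRaw("GY")),
    short_el(0x3004, 0x000c, "DS", charToRaw("0")),
    short_el(0x3004, 0x000e, "DS", charToRaw(sprintf("%g", scaling))),
    long_el(0x7fe0, 0x0010, "OW", u32r(stored_ints))
  )
  c(raw(128), charToRaw("DICM"), meta_len, meta, body)
}

write_dicom_fixture <- function(path, ...) {
  writeBin(dicom_fixture_bytes(...), path)
  path
}

# Random planned/measured pair on a compact grid with mild perturbations.
random_pair <- function(seed, extent = c(70, 70),
                        geometry = detector_geometry(8, 6, 5, 30)) {
  set.seed(seed)
  pert <- perturbation_spec(
    global_scale = runif(1, 0.985, 1.015),
    shift_mm = runif(2, -1.5, 1.5),
    noise_percent = runif(1, 0, 1.5),
    seed = seed + 1L
  )
  make_dose_pair(blob_spec(extent_mm = extent, seed = seed), pert, geometry)
}
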