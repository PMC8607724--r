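# Synthetic-data generators: dose-distribution pairs with controlled
# plan-vs-measurement discrepancies, plan cohorts with the parameter
# structure of a clinical QA database, and GP% time series with an optional
# level shift for process-monitoring studies. Everything is reproducible
# given (spec, seed).

#' Specification of a plan-vs-measurement discrepancy
#'
#' Perturbations are applied to the planned dose in a documented order:
#' global scale, rigid shift, hotspot, then per-point noise.
#'
#' @param global_scale multiplicative dose error (e.g. output drift).
#' @param shift_mm rigid translation `c(du, dv)` of the measured distribution
#'   relative to the plan, in mm.
#' @param noise_percent per-point Gaussian noise SD, percent of local dose.
#' @param hotspot optional `list(center = c(u, v), radius_mm, amplitude_percent)`:
#'   a smooth cosine-tapered dose bump, amplitude in percent of the plan
#'   maximum.
#' @param seed integer seed for the noise.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(global_scale = 1, shift_mm = c(0, 0),
                              noise_percent = 0, hotspot = NULL, seed = 1L) {
  stopifnot(global_scale > 0, length(shift_mm) == 2L, noise_percent >= 0)
  if (!is.null(hotspot)) {
    stopifnot(length(hotspot$center) == 2L, hotspot$radius_mm > 0)
  }
  structure(
    list(global_scale = global_scale, shift_mm = as.numeric(shift_mm),
         noise_percent = noise_percent, hotspot = hotspot, seed = seed),
    class = "perturbation_spec"
  )
}

#' Specification of a smooth Gaussian-blob dose field
#'
#' The planned distributions used by the synthetic pipeline are mixtures of
#' 2-5 Gaussian blobs on a regular grid — smooth, strictly positive fields
#' with realistic gradients but no anatomical structure.
#'
#' @param extent_mm grid extent `c(y, x)` in mm.
#' @param spacing_mm grid step (default 1.87 mm, the high-resolution planning
#'   grid).
#' @param peak_dose_Gy approximate maximum dose.
#' @param n_blobs number of blobs, or a range to draw from (default 2-5).
#' @param sigma_range_mm range of blob widths.
#' @param seed integer seed.
#' @return object of class `blob_spec`.
#' @export
blob_spec <- function(extent_mm = c(220, 660), spacing_mm = 1.87,
                      peak_dose_Gy = 2, n_blobs = c(2L, 5L),
                      sigma_range_mm = c(20, 80), seed = 1L) {
  stopifnot(all(extent_mm > 0), spacing_mm > 0, peak_dose_Gy > 0,
            all(n_blobs >= 1), sigma_range_mm[1] > 0,
            sigma_range_mm[2] >= sigma_range_mm[1])
  structure(
    list(extent_mm = as.numeric(extent_mm), spacing_mm = spacing_mm,
         peak_dose_Gy = peak_dose_Gy, n_blobs = as.integer(n_blobs),
         sigma_range_mm = as.numeric(sigma_range_mm), seed = seed),
    class = "blob_spec"
  )
}

# Build the planned grid from a blob spec (deterministic given spec).
# The grid is centred on (0, 0) so that it shares the unwrapped-detector
# coordinate frame (y = v, x = u).
make_blob_grid <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  ny <- max(2L, floor(spec$extent_mm[1] / spec$spacing_mm) + 1L)
  nx <- max(2L, floor(spec$extent_mm[2] / spec$spacing_mm) + 1L)
  y <- (seq_len(ny) - (ny + 1) / 2) * spec$spacing_mm
  x <- (seq_len(nx) - (nx + 1) / 2) * spec$spacing_mm
  with_seed(spec$seed, {
    nb <- if (length(spec$n_blobs) > 1L) {
      sample(seq.int(spec$n_blobs[1], spec$n_blobs[2]), 1L)
    } else spec$n_blobs
    values <- matrix(0, ny, nx)
    for (b in seq_len(nb)) {
      cy <- stats::runif(1, -0.5, 0.5) * max(y)
      cx <- stats::runif(1, -0.5, 0.5) * max(x)
      sy <- stats::runif(1, spec$sigma_range_mm[1], spec$sigma_range_mm[2])
      sx <- stats::runif(1, spec$sigma_range_mm[1], spec$sigma_range_mm[2])
      amp <- stats::runif(1, 0.4, 1)
      values <- values + amp * outer(exp(-(y - cy)^2 / (2 * sy^2)),
                                     exp(-(x - cx)^2 / (2 * sx^2)))
    }
    values <- values * spec$peak_dose_Gy / max(values)
    dose_grid(values, spacing_mm = spec$spacing_mm, origin_mm = c(y[1], x[1]))
  })
}

#' Generate a planned/measured dose pair
#'
#' Builds a smooth planned grid from `base` and manufactures a "measured"
#' point set by sampling the perturbed plan at the detector diodes.
#' Perturbations are applied in the order scale, shift, hotspot, noise;
#' doses pushed negative by noise are clipped at zero and counted in
#' `reference$meta$n_clipped`.
#'
#' @param base a [blob_spec] (or a ready-made 2D [dose_grid]).
#' @param perturbation a [perturbation_spec].
#' @param geometry a [detector_geometry] whose diode lattice must fit inside
#'   the grid.
#' @return list with `evaluation` (the planned [dose_grid]) and `reference`
#'   (the measured [dose_points]).
#' @export
make_dose_pair <- function(base = blob_spec(),
                           perturbation = perturbation_spec(),
                           geometry = detector_geometry()) {
  stopifnot(inherits(perturbation, "perturbation_spec"))
  grid <- if (inherits(base, "dose_grid")) base else make_blob_grid(base)
  if (length(dim(grid$values)) != 2L) {
    stop("dose pairs are generated on 2D (unwrapped-plane) grids", call. = FALSE)
  }
  ext <- grid_extent(grid)
  center <- colMeans(ext)
  pos <- detector_positions(geometry)
  y <- center[1] + pos$v_mm
  x <- center[2] + pos$u_mm
  check_fit(list(y = y, x = x), ext, c("y", "x"))

  # scale, then shift: measured dose at p is the scaled plan at p - shift
  sy <- perturbation$shift_mm[2]   # v component
  sx <- perturbation$shift_mm[1]   # u component
  d <- perturbation$global_scale *
    interp_bilinear(grid$values, grid$spacing_mm, grid$origin_mm, y - sy, x - sx)
  n_outside <- sum(is.na(d))
  d[is.na(d)] <- 0

  hs <- perturbation$hotspot
  if (!is.null(hs)) {
    du <- pos$u_mm - hs$center[1]
    dv <- pos$v_mm - hs$center[2]
    r <- sqrt(du^2 + dv^2)
    bump <- ifelse(r < hs$radius_mm,
                   hs$amplitude_percent / 100 * max(grid$values) *
                     cos(pi * r / (2 * hs$radius_mm))^2,
                   0)
    d <- d + bump
  }

  n_clipped <- 0L
  if (perturbation$noise_percent > 0) {
    d <- with_seed(perturbation$seed,
                   d * (1 + stats::rnorm(length(d), 0, perturbation$noise_percent / 100)))
    n_clipped <- sum(d < 0)
    if (n_clipped > 0L) {
      warning(n_clipped, " dose point(s) clipped at 0 after noise", call. = FALSE)
      d[d < 0] <- 0
    }
  }

  # points are returned in the evaluation grid's frame (cylinder centre at
  # the grid centre), so the pair can be fed straight to compute_gamma()
  reference <- dose_points(x, y, d,
                           meta = list(n_clipped = n_clipped,
                                       n_outside = n_outside))
  list(evaluation = grid, reference = reference)
}

# Cohort parameter distributions: per-parameter mean/SD and range used by
# the truncated-normal sampler.
default_parameter_table <- function() {
  data.frame(
    parameter = c("dose_per_fraction_cGy", "mf", "pitch", "gantry_period_s",
                  "total_treatment_time_s", "min_lot_floor_ms", "mean_lot_ms",
                  "sd_lot_ms", "couch_travel_mm"),
    mean = c(219.8, 1.68, 0.39, 20.1, 299.7, 18.2, 236.3, 107.9, 160.2),
    sd   = c(62.6, 0.28, 0.06, 7.3, 141.0, 1.1, 82.7, 44.2, 88.9),
    min  = c(160.0, 1.10, 0.12, 11.8, 66.3, 18.0, 57.8, 21.1, 31.1),
    max  = c(500.0, 2.79, 0.48, 52.8, 1241.3, 36.4, 617.1, 316.1, 895.2),
    stringsAsFactors = FALSE
  )
}

# Site sampling weights of the reference clinical population.
default_site_probs <- function() {
  counts <- c(abdomen = 28, brain = 32, head_and_neck = 77, lungs = 71,
              pelvis = 84, prostate = 52, others = 41)
  counts / sum(counts)
}

default_gp_model <- function() {
  list("3G2" = c(mean = 97.6, sd = 2.6),
       "3L2" = c(mean = 90.9, sd = 5.0),
       "3G3" = c(mean = 99.2, sd = 1.3),
       "3L3" = c(mean = 96.0, sd = 3.0))
}

#' Specification of a synthetic QA cohort
#'
#' Defaults reproduce the statistical structure of a two-year clinical QA
#' database: site mix, planning-parameter distributions (truncated normals
#' within the observed ranges), field-width split 2.1/92.0/5.9% across
#' 10/25/50 mm, and per-criteria GP% models. Derived quantities are kept
#' internally consistent: TTDF = time / dose per fraction and couch speed =
#' couch travel / time are recomputed from the sampled primitives.
#'
#' @param n_plans cohort size (default 395).
#' @param site_probs named site probabilities (must sum to 1).
#' @param parameters parameter table (`parameter, mean, sd, min, max`).
#' @param fw_probs probabilities of the 10/25/50 mm field widths.
#' @param gp_model named list per criteria label with `c(mean, sd)` of the
#'   GP% distribution (clipped to `[0, 100]` after sampling).
#' @param site_effects named GP% offsets per site (default all zero; the
#'   clinical data fix no per-site means, so these are free parameters).
#' @param gp_latent_rho correlation loading of the shared per-plan latent
#'   factor across criteria (measurement quality is plan-specific).
#' @param changepoint optional `list(index, delta)`: GP% level shift of
#'   `delta` applied to all criteria after record `index` (date order).
#' @param n_lot number of leaf-open-time values simulated per plan.
#' @param start_date,end_date delivery date span (default two years).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_plans = 395,
                        site_probs = default_site_probs(),
                        parameters = default_parameter_table(),
                        fw_probs = c(`10` = 0.021, `25` = 0.920, `50` = 0.059),
                        gp_model = default_gp_model(),
                        site_effects = NULL,
                        gp_latent_rho = 0.7,
                        changepoint = NULL,
                        n_lot = 120L,
                        start_date = as.Date("2018-06-01"),
                        end_date = as.Date("2020-06-01"),
                        seed = 1L) {
  if (abs(sum(site_probs) - 1) > 1e-8) stop("site probabilities must sum to 1", call. = FALSE)
  if (any(parameters$sd < 0)) stop("parameter SDs must be non-negative", call. = FALSE)
  if (any(parameters$min >= parameters$max)) {
    bad <- parameters$parameter[parameters$min >= parameters$max][1]
    stop("infeasible parameter range (min >= max) for ", bad, call. = FALSE)
  }
  if (abs(sum(fw_probs) - 1) > 1e-8) stop("field-width probabilities must sum to 1", call. = FALSE)
  if (!is.null(changepoint)) stopifnot(changepoint$index >= 0, changepoint$index <= n_plans)
  if (is.null(site_effects)) {
    site_effects <- stats::setNames(rep(0, length(site_probs)), names(site_probs))
  }
  structure(
    list(n_plans = as.integer(n_plans), site_probs = site_probs,
         parameters = parameters, fw_probs = fw_probs, gp_model = gp_model,
         site_effects = site_effects, gp_latent_rho = gp_latent_rho,
         changepoint = changepoint, n_lot = as.integer(n_lot),
         start_date = start_date, end_date = end_date, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic plan cohort with QA results
#'
#' Samples plan records and per-plan QA passing rates from a [cohort_spec].
#' Planning parameters come from truncated normals within the specified
#' ranges; leaf-open-time arrays are simulated per plan and their descriptor
#' columns recomputed from the arrays, so every record satisfies the
#' plan-record invariants by construction.
#'
#' @param spec a [cohort_spec].
#' @return list with `plans` (data frame of plan records), `lots` (long data
#'   frame `plan_id, lot_ms`) and `qa` (data frame of QA records with
#'   `gp_3G2`, `gp_3L2`, `gp_3G3`, `gp_3L3` and a `clinical` flag).
#' @export
make_plan_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_plans
  pt <- spec$parameters
  row_of <- function(p) pt[pt$parameter == p, ]
  draw <- function(p, n) {
    r <- row_of(p)
    rtruncnorm(n, r$mean, r$sd, r$min, r$max)
  }
  with_seed(spec$seed, {
    site <- sample(names(spec$site_probs), n, replace = TRUE,
                   prob = spec$site_probs)
    fw <- sample(as.numeric(names(spec$fw_probs)), n, replace = TRUE,
                 prob = spec$fw_probs)
    dose <- draw("dose_per_fraction_cGy", n)
    mf <- draw("mf", n)
    pitch <- draw("pitch", n)
    gantry <- draw("gantry_period_s", n)
    time_s <- draw("total_treatment_time_s", n)
    travel <- draw("couch_travel_mm", n)
    mean_lot <- draw("mean_lot_ms", n)
    sd_lot <- draw("sd_lot_ms", n)
    lot_floor <- row_of("min_lot_floor_ms")$min

    lots <- vector("list", n)
    desc <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      lot <- rtruncnorm(spec$n_lot, mean_lot[i], sd_lot[i], lower = lot_floor)
      # a small fraction of near-floor openings: binary-MLC leaves that
      # barely open, which is what drives clinical min-LOT values to sit
      # just above the mechanical floor
      at_floor <- stats::runif(spec$n_lot) < 0.05
      lot[at_floor] <- lot_floor + stats::rexp(sum(at_floor), rate = 1 / 1.5)
      lots[[i]] <- lot
      d <- lot_descriptors(lot)
      desc[i, ] <- c(d$min_lot_ms, d$mean_lot_ms, d$max_lot_ms, d$sd_lot_ms)
    }

    dates <- sort(spec$start_date +
                    round(stats::runif(n, 0,
                                       as.numeric(spec$end_date - spec$start_date))))
    plan_id <- sprintf("plan_%04d", seq_len(n))

    plans <- data.frame(
      plan_id = plan_id, site = site, date = dates,
      dose_per_fraction_cGy = dose, mf = mf, pitch = pitch,
      field_width_mm = fw, gantry_period_s = gantry,
      total_treatment_time_s = time_s,
      couch_speed_mm_s = travel / time_s, couch_travel_mm = travel,
      ttdf_s_per_cGy = compute_ttdf(time_s, dose),
      min_lot_ms = desc[, 1], mean_lot_ms = desc[, 2],
      max_lot_ms = desc[, 3], sd_lot_ms = desc[, 4],
      stringsAsFactors = FALSE
    )

    z <- stats::rnorm(n)
    rho <- spec$gp_latent_rho
    site_off <- spec$site_effects[site]
    site_off[is.na(site_off)] <- 0
    post_cp <- if (!is.null(spec$changepoint)) {
      seq_len(n) > spec$changepoint$index
    } else rep(FALSE, n)
    qa <- data.frame(plan_id = plan_id, date = dates, stringsAsFactors = FALSE)
    for (lab in names(spec$gp_model)) {
      m <- spec$gp_model[[lab]]
      raw <- m[["mean"]] +
        m[["sd"]] * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n)) +
        site_off +
        ifelse(post_cp, spec$changepoint$delta, 0)
      qa[[paste0("gp_", lab)]] <- pmin(100, pmax(0, raw))
    }
    qa$clinical <- qa$gp_3G2 > 90

    lots_long <- data.frame(
      plan_id = rep(plan_id, each = spec$n_lot),
      lot_ms = unlist(lots)
    )
    list(plans = plans, lots = lots_long, qa = qa)
  })
}

#' Generate an ordered GP% series for process monitoring
#'
#' Truncated-normal GP% values (bounded to `[0, 100]`) with an optional level
#' shift of `delta` after `changepoint_index`, date-stamped to fill four
#' six-month monitoring periods.
#'
#' @param n series length (`n = 0` yields an empty series).
#' @param mean,sd GP% moments before the changepoint (`sd >= 0`).
#' @param changepoint_index last index of the pre-shift regime (0 = no
#'   pre-shift records, `n` = no shift at all).
#' @param delta level shift applied after the changepoint.
#' @param sd_after SD after the changepoint (defaults to `sd`).
#' @param seed integer seed.
#' @param start_date first delivery date.
#' @param n_periods number of six-month periods the dates span.
#' @return data frame of QA records (`plan_id`, `date`, `gp_3G2`) with the
#'   period boundary dates attached as attribute `"period_boundaries"`.
#' @export
make_gp_series <- function(n, mean = 97.6, sd = 2.6, changepoint_index = n,
                           delta = 0, sd_after = sd, seed = 1L,
                           start_date = as.Date("2018-06-01"), n_periods = 4L) {
  if (sd < 0 || sd_after < 0) stop("sd must be non-negative", call. = FALSE)
  if (changepoint_index < 0 || changepoint_index > n) {
    stop("changepoint_index must lie in [0, n]", call. = FALSE)
  }
  boundaries <- seq(start_date, by = "6 months", length.out = n_periods + 1L)
  if (n == 0L) {
    out <- data.frame(plan_id = character(0), date = as.Date(character(0)),
                      gp_3G2 = numeric(0))
    attr(out, "period_boundaries") <- boundaries
    return(out)
  }
  gp <- with_seed(seed, {
    n_pre <- changepoint_index
    c(rtruncnorm(n_pre, mean, sd, 0, 100),
      rtruncnorm(n - n_pre, mean + delta, sd_after, 0, 100))
  })
  span_days <- as.numeric(boundaries[n_periods + 1L] - start_date)
  dates <- start_date + floor((seq_len(n) - 1) * span_days / n)
  out <- data.frame(plan_id = sprintf("plan_%04d", seq_len(n)),
                    date = dates, gp_3G2 = gp, stringsAsFactors = FALSE)
  attr(out, "period_boundaries") <- boundaries
  out
}
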