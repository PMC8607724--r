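test_that("generators are bit-reproducible given spec and seed", {
  s1 <- make_plan_cohort(cohort_spec(n_plans = 50, seed = 101))
  s2 <- make_plan_cohort(cohort_spec(n_plans = 50, seed = 101))
  expect_identical(s1, s2)
  s3 <- make_plan_cohort(cohort_spec(n_plans = 50, seed = 102))
  expect_false(identical(s1$qa$gp_3G2, s3$qa$gp_3G2))

  p1 <- make_dose_pair(blob_spec(extent_mm = c(70, 70), seed = 3),
                       perturbation_spec(noise_percent = 2, seed = 4),
                       small_geometry())
  p2 <- make_dose_pair(blob_spec(extent_mm = c(70, 70), seed = 3),
                       perturbation_spec(noise_percent = 2, seed = 4),
                       small_geometry())
  expect_identical(p1, p2)

  g1 <- make_gp_series(100, seed = 7)
  g2 <- make_gp_series(100, seed = 7)
  expect_identical(g1, g2)
})

test_that("generated cohorts satisfy the plan-record invariants by construction", {
  for (seed in c(11, 12, 13)) {
    sim <- make_plan_cohort(cohort_spec(n_plans = 80, seed = seed))
    expect_silent(tomoqa:::validate_plan_records(sim$plans))
    expect_true(all(sim$plans$min_lot_ms <= sim$plans$mean_lot_ms))
    expect_true(all(sim$plans$mean_lot_ms <= sim$plans$max_lot_ms))
    # derived fields are internally consistent
    expect_equal(sim$plans$ttdf_s_per_cGy,
                 sim$plans$total_treatment_time_s / sim$plans$dose_per_fraction_cGy)
    expect_equal(sim$plans$couch_speed_mm_s,
                 sim$plans$couch_travel_mm / sim$plans$total_treatment_time_s)
    expect_true(all(sim$qa$gp_3G2 >= 0 & sim$qa$gp_3G2 <= 100))
    expect_identical(sim$qa$clinical, sim$qa$gp_3G2 > 90)
  }
})

test_that("identity perturbation reproduces the plan exactly at every diode", {
  pair <- make_dose_pair(blob_spec(extent_mm = c(80, 80), seed = 21),
                         perturbation_spec(), small_geometry())
  res <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(3, 2))
  expect_true(all(res$gamma_values[res$evaluated] == 0))
})

test_that("a 3.1% global scaling fails every near-maximum reference point", {
  # single broad centred blob so that diodes sample very close to D_norm
  sp <- 1.87
  n <- 45
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  vals <- 2 * exp(-outer(ax^2, ax^2, "+") / (2 * 40^2))
  g <- dose_grid(vals, spacing_mm = sp, origin_mm = c(ax[1], ax[1]))
  pair <- make_dose_pair(g, perturbation_spec(global_scale = 1.031),
                         detector_geometry(8, 2, 2, 16))
  res <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(3, 2))
  d_norm <- max(g$values)
  hot <- pair$reference$points$dose_Gy > 1.0301 * d_norm
  expect_gt(sum(hot), 0)
  expect_true(all(res$gamma_values[hot] > 1))
  expect_lt(res$gp_percent, 100)
})

test_that("rigid shifts pass or fail according to the DTA criterion", {
  base <- blob_spec(extent_mm = c(80, 80), sigma_range_mm = c(20, 30), seed = 22)
  geom <- small_geometry()
  shifted_19 <- make_dose_pair(base, perturbation_spec(shift_mm = c(1.9, 0)), geom)
  res <- compute_gamma(shifted_19$reference, shifted_19$evaluation,
                       gamma_criteria(3, 2))
  expect_equal(res$gp_percent, 100)
  # the matching position sits 1.9 mm away with an exact dose match
  expect_true(all(res$gamma_values[res$evaluated] <= 1.9 / 2 + 1e-9))

  shifted_4 <- make_dose_pair(base, perturbation_spec(shift_mm = c(4, 0)), geom)
  res4 <- compute_gamma(shifted_4$reference, shifted_4$evaluation,
                        gamma_criteria(3, 2))
  expect_lt(res4$gp_percent, 100)
})

test_that("cohort GP% means land on the clipped-normal realized moments", {
  spec <- cohort_spec(n_plans = 1000, seed = 23)
  sim <- make_plan_cohort(spec)
  for (lab in c("3G2", "3L2")) {
    m <- spec$gp_model[[lab]]
    target <- clipnorm_mean(m[["mean"]], m[["sd"]])
    se <- m[["sd"]] / sqrt(1000)
    expect_lt(abs(mean(sim$qa[[paste0("gp_", lab)]]) - target), 3 * se)
  }
})

test_that("zero-SD cohorts collapse to identical numeric parameters", {
  pt <- tomoqa:::default_parameter_table()
  pt$sd <- 0
  sim <- make_plan_cohort(cohort_spec(n_plans = 5, parameters = pt, seed = 24,
                                      gp_model = list("3G2" = c(mean = 97, sd = 0),
                                                      "3L2" = c(mean = 91, sd = 0),
                                                      "3G3" = c(mean = 99, sd = 0),
                                                      "3L3" = c(mean = 96, sd = 0))))
  for (p in c("dose_per_fraction_cGy", "mf", "pitch", "gantry_period_s",
              "total_treatment_time_s", "couch_travel_mm")) {
    expect_equal(sd(sim$plans[[p]]), 0)
  }
  expect_true(all(sim$qa$gp_3G2 == 97))
})

test_that("infeasible cohort specs are rejected", {
  pt <- tomoqa:::default_parameter_table()
  pt$min[1] <- pt$max[1] + 1
  expect_error(cohort_spec(parameters = pt), "infeasible")
  expect_error(cohort_spec(site_probs = c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("GP% series honor length, truncation, changepoint and dating", {
  empty <- make_gp_series(0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_length(attr(empty, "period_boundaries"), 5)

  ser <- make_gp_series(400, mean = 97, sd = 2, changepoint_index = 100,
                        delta = -3, seed = 31)
  expect_true(all(ser$gp_3G2 <= 100))
  expect_false(is.unsorted(ser$date))
  expect_lt(mean(ser$gp_3G2[101:400]), mean(ser$gp_3G2[1:100]))
  expect_equal(mean(ser$gp_3G2[1:100]) - mean(ser$gp_3G2[101:400]), 3,
               tolerance = 0.5)
  b <- attr(ser, "period_boundaries")
  expect_true(all(ser$date >= b[1] & ser$date < b[5]))
  expect_error(make_gp_series(10, sd = -1, seed = 1), "non-negative")
  expect_error(make_gp_series(10, changepoint_index = 11, seed = 1), "\\[0, n\\]")
})

test_that("perturbation and blob specs validate their fields", {
  expect_error(perturbation_spec(noise_percent = -1))
  expect_error(perturbation_spec(hotspot = list(center = c(0, 0), radius_mm = 0)))
  expect_error(blob_spec(spacing_mm = 0))
  # hotspot adds dose inside its radius only
  g <- dose_grid(matrix(1, 41, 41), spacing_mm = 2, origin_mm = c(-40, -40))
  pair <- make_dose_pair(g, perturbation_spec(
    hotspot = list(center = c(0, 0), radius_mm = 6, amplitude_percent = 10)),
    detector_geometry(8, 4, 4, 24))
  r <- sqrt(pair$reference$points$u_mm^2 + pair$reference$points$v_mm^2)
  expect_true(all(pair$reference$points$dose_Gy[r >= 6] == 1))
  expect_true(all(pair$reference$points$dose_Gy[r < 5.9] > 1))
})
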