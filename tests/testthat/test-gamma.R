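test_that("criteria validation enforces the documented invariants", {
  expect_error(gamma_criteria(dd_percent = 0), "dd_percent")
  expect_error(gamma_criteria(dta_mm = -1), "dta_mm")
  expect_error(gamma_criteria(threshold_percent = 100), "threshold")
  expect_error(gamma_criteria(threshold_percent = 0, normalization = "local"),
               "local normalization")
  expect_error(gamma_criteria(max_search_radius_mm = 1), "max_search_radius")
  expect_error(gamma_criteria(interp_step_mm = 0.5), "interp_step")
})

test_that("identical distributions give gamma 0 everywhere and GP% = 100", {
  pair <- make_dose_pair(blob_spec(extent_mm = c(80, 80), seed = 11),
                         perturbation_spec(), small_geometry())
  for (cr in standard_criteria_sets()) {
    res <- compute_gamma(pair$reference, pair$evaluation, cr)
    expect_equal(max(res$gamma_values[res$evaluated]), 0)
    expect_equal(res$gp_percent, 100)
  }
})

test_that("on a uniform field gamma equals the pure dose-difference term", {
  g <- dose_grid(matrix(1, 30, 30), spacing_mm = 2)
  # DTA search cannot help on a flat field: gamma = |dd| / (3% of D)
  r1 <- compute_gamma(dose_points(29, 29, 1.03), g, gamma_criteria(3, 2))
  expect_equal(r1$gamma_values, 1, tolerance = 1e-9)
  expect_equal(r1$gp_percent, 100)  # gamma exactly 1 passes
  r2 <- compute_gamma(dose_points(29, 29, 1.031), g, gamma_criteria(3, 2))
  expect_gt(r2$gamma_values, 1)
  expect_equal(r2$gp_percent, 0)
})

test_that("a 2 mm shifted steep ramp passes 3%/2mm but fails 3%/1mm in the interior", {
  nx <- 27
  x <- (seq_len(nx) - 1) * 0.5           # 0..13 mm
  vals <- matrix(rep(0.05 + 0.15 * x, each = 5), nrow = 5, byrow = FALSE)
  g <- dose_grid(vals, spacing_mm = c(2, 0.5))
  xi <- seq(3, 10, by = 0.5)
  ref <- dose_points(u_mm = xi, v_mm = rep(4, length(xi)),
                     dose_Gy = 0.05 + 0.15 * (xi - 2))
  res2 <- compute_gamma(ref, g, gamma_criteria(3, 2, threshold_percent = 0))
  expect_true(all(res2$gamma_values <= 1))
  res1 <- compute_gamma(ref, g, gamma_criteria(3, 1, threshold_percent = 0))
  expect_true(all(res1$gamma_values > 1))
  # closed-form quadratic trade-off at 2 mm DTA: min_u u^2/4 + 6.25 (2-u)^2
  # is attained at u = 25/13 with value 25/26
  expect_equal(res2$gamma_values, rep(sqrt(25 / 26), length(xi)), tolerance = 1e-6)
})

test_that("local gamma is twice the global gamma at half the normalization dose", {
  # flat 1.06 Gy region around the point; remote peak sets D_norm = 2 Gy
  vals <- matrix(1.06, 41, 41)
  vals[36:41, 36:41] <- 2
  g <- dose_grid(vals, spacing_mm = 2)
  ref <- dose_points(20, 20, 1.0)   # 50% of D_norm, 3%-of-D_norm discrepancy
  gg <- compute_gamma(ref, g, gamma_criteria(3, 2, normalization = "global"))
  gl <- compute_gamma(ref, g, gamma_criteria(3, 2, normalization = "local"))
  expect_equal(gg$gamma_values, 1, tolerance = 1e-9)
  expect_equal(gl$gamma_values, 2 * gg$gamma_values, tolerance = 1e-9)
})

test_that("points below the dose threshold are excluded from GP% but reported", {
  vals <- matrix(0.02, 30, 30); vals[10:20, 10:20] <- 2
  g <- dose_grid(vals, spacing_mm = 2)
  # points 3 and 4 sit in the low-dose plateau below the 10% threshold: they
  # are reported but must enter neither numerator nor denominator
  ref <- dose_points(c(28, 30, 2, 4), c(28, 30, 2, 4), c(2, 2, 0.05, 0.08))
  res <- compute_gamma(ref, g, gamma_criteria(3, 2, 10))
  expect_equal(sum(res$evaluated), 2)
  expect_length(res$gamma_values, 4)
  expect_equal(res$gp_percent, 100)
  expect_equal(passing_rate(res), 100)
})

test_that("passing rate counts gamma <= 1 over evaluated points only", {
  fake <- structure(
    list(gamma_values = c(0.2, 0.8, 1.0, 1.2), evaluated = rep(TRUE, 4),
         n_evaluated = 4L, n_passing = 3L, gp_percent = 75),
    class = "gamma_result")
  expect_equal(passing_rate(fake), 75)
  fake$gamma_values <- rep(0, 4)
  expect_equal(passing_rate(fake), 100)
  fake$evaluated <- c(FALSE, FALSE, TRUE, TRUE)
  fake$gamma_values <- c(9, 9, 0.5, 0.5)
  expect_equal(passing_rate(fake), 100)
})

test_that("an all-below-threshold comparison errors rather than reporting 0 or 100", {
  g <- dose_grid(matrix(c(rep(0.05, 360), rep(2, 40)), 20, 20), spacing_mm = 2)
  ref <- dose_points(c(2, 4), c(2, 4), c(0.01, 0.02))
  expect_error(compute_gamma(ref, g), "threshold")
})

test_that("engine gamma matches the brute-force oracle on random pairs", {
  for (seed in c(21, 22, 23)) {
    pair <- random_pair(seed)
    cr <- gamma_criteria(3, 2, 10, if (seed %% 2) "global" else "local")
    eng <- compute_gamma(pair$reference, pair$evaluation, cr)
    orc <- brute_gamma(pair$reference, pair$evaluation, cr)
    expect_lt(max(abs(eng$gamma_values - orc)), 1e-6)
  }
})

test_that("enlarging dta or dd never increases gamma; GP% is monotone", {
  pair <- random_pair(31)
  base <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(3, 2))
  wider_dta <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(3, 3))
  wider_dd <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(4, 2))
  expect_true(all(wider_dta$gamma_values <= base$gamma_values + 1e-9))
  expect_true(all(wider_dd$gamma_values <= base$gamma_values + 1e-9))
  expect_gte(wider_dta$gp_percent, base$gp_percent)
  expect_gte(wider_dd$gp_percent, base$gp_percent)
})

test_that("global gamma is scale invariant and GP% is translation equivariant", {
  pair <- random_pair(32)
  res <- compute_gamma(pair$reference, pair$evaluation, gamma_criteria(3, 2))
  k <- 2.37
  ref_s <- dose_points(pair$reference$points$u_mm, pair$reference$points$v_mm,
                       k * pair$reference$points$dose_Gy)
  ev_s <- dose_grid(k * pair$evaluation$values, pair$evaluation$spacing_mm,
                    pair$evaluation$origin_mm)
  res_s <- compute_gamma(ref_s, ev_s, gamma_criteria(3, 2))
  expect_equal(res_s$gamma_values, res$gamma_values, tolerance = 1e-9)

  t <- c(13.5, -7.25)
  ref_t <- dose_points(pair$reference$points$u_mm + t[2],
                       pair$reference$points$v_mm + t[1],
                       pair$reference$points$dose_Gy)
  ev_t <- dose_grid(pair$evaluation$values, pair$evaluation$spacing_mm,
                    pair$evaluation$origin_mm + t)
  res_t <- compute_gamma(ref_t, ev_t, gamma_criteria(3, 2))
  expect_equal(res_t$gp_percent, res$gp_percent)
  expect_equal(res_t$gamma_values, res$gamma_values, tolerance = 1e-9)
})

test_that("halving the search lattice step changes GP% by less than 0.1 points", {
  pair <- random_pair(33)
  coarse <- compute_gamma(pair$reference, pair$evaluation,
                          gamma_criteria(3, 2, interp_step_mm = 0.2))
  fine <- compute_gamma(pair$reference, pair$evaluation,
                        gamma_criteria(3, 2, interp_step_mm = 0.1))
  expect_lt(abs(coarse$gp_percent - fine$gp_percent), 0.1)
})

test_that("batch analysis tabulates GP% per case and criteria with the expected orderings", {
  ident <- make_dose_pair(blob_spec(extent_mm = c(80, 80), seed = 41),
                          perturbation_spec(), small_geometry())
  pert <- make_dose_pair(blob_spec(extent_mm = c(80, 80), seed = 41),
                         perturbation_spec(shift_mm = c(1.2, 0.5),
                                           noise_percent = 1.8, seed = 42),
                         small_geometry())
  tab <- batch_analyze(list(ident = ident, pert = pert))
  expect_identical(dim(tab), c(2L, 5L))
  expect_true(all(tab[tab$case == "ident", -1] == 100))
  # wider DTA never lowers GP%; local normalization never exceeds global
  expect_gte(tab[2, "3G3"], tab[2, "3G2"])
  expect_gte(tab[2, "3L3"], tab[2, "3L2"])
  expect_lte(tab[2, "3L2"], tab[2, "3G2"])
  expect_lte(tab[2, "3L3"], tab[2, "3G3"])
})

test_that("a failing case aborts the batch with its identifier", {
  g <- dose_grid(matrix(c(rep(0.05, 360), rep(2, 40)), 20, 20), spacing_mm = 2)
  bad <- list(reference = dose_points(2, 2, 0.01), evaluation = g)
  expect_error(batch_analyze(list(bad_case = bad)), "bad_case")
})
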