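test_that("csv-grid files read back the stored doses and round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# spacing_mm: 1.87 1.87", "# origin_mm: 0 0", "1,2", "3,4"), path)
  g <- read_dose_grid(path)
  expect_identical(dim(g$values), c(2L, 2L))
  expect_equal(max(g$values), 4)
  expect_equal(g$spacing_mm, c(1.87, 1.87))

  g2 <- dose_grid(matrix(runif(30, 0, 3), 5, 6), spacing_mm = c(2, 1.87),
                  origin_mm = c(-4, 7.3))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dose_grid(g2, p1)
  rt <- read_dose_grid(p1)
  expect_equal(rt$spacing_mm, g2$spacing_mm)
  expect_equal(rt$origin_mm, g2$origin_mm)
  expect_equal(rt$values, g2$values, tolerance = 1e-5)  # 6 significant digits
  write_dose_grid(rt, p2)
  expect_identical(readLines(p1), readLines(p2))        # stable at precision
})

test_that("csv-grid reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), path)
  expect_error(read_dose_grid(path), "spacing_mm")
  expect_error(read_dose_grid(file.path(tempdir(), "nope.csv")), "does not exist")
})

test_that("a hand-built DICOM RT Dose fixture reads to scaled Gy doses", {
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(path, stored_ints = c(1000L, 2000L, 3000L, 4000L),
                      scaling = 0.001, spacing = c(1.5, 2.5), ipp = c(10, 20, 0))
  g <- read_dose_grid(path, format = "dicom-rtdose")
  # pixel order is row-major within the frame
  expect_equal(g$values, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(g$spacing_mm, c(1.5, 2.5))
  expect_equal(g$origin_mm, c(20, 10))  # (y, x) from image position (x, y, z)
})

test_that("DICOM reader rejects non-dose and non-DICOM inputs", {
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(path, modality = "CT")
  expect_error(read_dose_grid(path, format = "dicom-rtdose"), "RT Dose")
  plain <- withr::local_tempfile()
  writeLines("not dicom at all, just text padding beyond 140 bytes ............................................................................", plain)
  expect_error(read_dose_grid(plain, format = "dicom-rtdose"), "DICM")
})

test_that("DICOM round-trip preserves 2D and 3D grids to quantization accuracy", {
  g2d <- dose_grid(matrix(runif(12, 0, 2.5), 3, 4), spacing_mm = c(2, 1.87),
                   origin_mm = c(-5, 3))
  p <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g2d, p, format = "dicom-rtdose")
  rt <- read_dose_grid(p)
  expect_equal(rt$values, g2d$values, tolerance = 1e-8)
  expect_equal(rt$spacing_mm, g2d$spacing_mm)
  expect_equal(rt$origin_mm, g2d$origin_mm)

  g3d <- dose_grid(array(runif(3 * 4 * 5, 0, 2), c(3, 4, 5)),
                   spacing_mm = c(2.5, 1.87, 1.87), origin_mm = c(-1, -2, -3))
  write_dose_grid(g3d, p, format = "dicom-rtdose")
  rt3 <- read_dose_grid(p)
  expect_equal(rt3$values, g3d$values, tolerance = 1e-8)
  expect_equal(rt3$spacing_mm, g3d$spacing_mm)
  expect_equal(rt3$origin_mm, g3d$origin_mm)
})

test_that("dose_grid enforces its invariants", {
  expect_error(dose_grid(matrix(-1, 2, 2)), "non-negative")
  expect_error(dose_grid(matrix(1, 1, 2)), "at least 2 samples")
  expect_error(dose_grid(matrix(1, 2, 2), spacing_mm = 0), "positive")
})

test_that("detector sampling of a uniform field returns the uniform dose", {
  g2 <- dose_grid(matrix(2, 40, 40), spacing_mm = 2)
  pts <- sample_detector(g2, small_geometry())
  expect_true(all(pts$points$dose_Gy == 2))

  g3 <- dose_grid(array(2, c(30, 30, 30)), spacing_mm = 2)
  pts3 <- sample_detector(g3, detector_geometry(10, 8, 5, 40))
  expect_true(all(abs(pts3$points$dose_Gy - 2) < 1e-12))
})

test_that("detector sampling is exact on a field linear in z (trilinear closed form)", {
  nz <- 31
  z <- (seq_len(nz) - 1) * 2
  vals <- array(rep(0.5 + 0.01 * z, times = 30 * 30), c(nz, 30, 30))
  g <- dose_grid(vals, spacing_mm = 2)
  geom <- detector_geometry(10, 7, 5, 28)
  pts <- sample_detector(g, geom)
  z_center <- mean(range(z))
  expected <- 0.5 + 0.01 * (z_center + pts$points$v_mm)
  expect_equal(pts$points$dose_Gy, expected, tolerance = 1e-12)
})

test_that("a detector larger than the grid errors naming the offending axis", {
  g <- dose_grid(matrix(1, 10, 50), spacing_mm = 2)  # y extent 18 mm only
  expect_error(sample_detector(g, detector_geometry(10, 8, 5, 40)), "\\by axis\\b")
})

test_that("output correction scales doses, composes multiplicatively, and is bounded", {
  p <- dose_points(c(0, 1), c(0, 0), c(1, 2))
  expect_equal(apply_output_correction(p, 1)$points$dose_Gy, c(1, 2))
  p2 <- apply_output_correction(p, 1.02)
  expect_equal(p2$points$dose_Gy, c(1.02, 2.04))
  expect_equal(p2$meta$output_correction, 1.02)
  ab <- apply_output_correction(apply_output_correction(p, 1.03), 0.97)
  once <- apply_output_correction(p, 1.03 * 0.97)
  expect_equal(ab$points$dose_Gy, once$points$dose_Gy)
  expect_equal(ab$meta$output_correction, once$meta$output_correction)
  expect_error(apply_output_correction(p, 0.2), "0.5, 1.5")
  expect_error(apply_output_correction(p, 1.5), "0.5, 1.5")
})

test_that("csv-points round-trips doses, coordinates and metadata", {
  p <- dose_points(c(-3.25, 4.5), c(1, -2), c(0.51, 1.75),
                   meta = list(detector_id = "AC-042", output_correction = 1.013))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_points(p, path)
  rt <- read_dose_points(path)
  expect_equal(rt$points, p$points, tolerance = 1e-6)
  expect_equal(rt$meta$detector_id, "AC-042")
  expect_equal(rt$meta$output_correction, 1.013)
  expect_error(read_dose_points(withr::local_tempfile(fileext = ".csv")),
               "does not exist")
})

test_that("dose point sets enforce their invariants", {
  expect_error(dose_points(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(dose_points(Inf, 0, 1), "finite")
  expect_error(dose_points(0, 0, -0.1), "non-negative")
})
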