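#' Cylindrical diode-array geometry
#'
#' An idealised helical-diode-array layout: diodes on a cylinder of given
#' radius, regularly spaced along the axis and around the circumference. The
#' defaults (105 mm radius, 10 mm spacing both ways, 210 mm axial extent)
#' describe a generic cylindrical array; all package operations work for any
#' valid geometry.
#'
#' Unwrap convention: angle 0 at the top of the cylinder, increasing
#' clockwise as seen from the gantry; `u = radius * angle` (arc length),
#' `v` = axial position, both centred on the cylinder midpoint.
#'
#' @param cylinder_radius_mm cylinder radius (> 0).
#' @param spacing_axial_mm,spacing_circ_mm diode spacing along the axis and
#'   along the circumference (> 0).
#' @param axial_extent_mm detector length along the axis (> 0).
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(cylinder_radius_mm = 105,
                              spacing_axial_mm = 10,
                              spacing_circ_mm = 10,
                              axial_extent_mm = 210) {
  vals <- c(cylinder_radius_mm, spacing_axial_mm, spacing_circ_mm, axial_extent_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all detector geometry dimensions must be positive", call. = FALSE)
  }
  structure(
    list(cylinder_radius_mm = cylinder_radius_mm,
         spacing_axial_mm = spacing_axial_mm,
         spacing_circ_mm = spacing_circ_mm,
         axial_extent_mm = axial_extent_mm),
    class = "detector_geometry"
  )
}

#' Diode positions of a detector geometry
#'
#' @param geometry a [detector_geometry].
#' @return data frame with unwrapped coordinates `u_mm`, `v_mm` and the
#'   underlying cylinder angle `theta_rad` (0 = top, clockwise from gantry
#'   view) and axial offset `z_mm`.
#' @export
detector_positions <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  R <- geometry$cylinder_radius_mm
  n_ax <- floor(geometry$axial_extent_mm / geometry$spacing_axial_mm) + 1L
  z <- (seq_len(n_ax) - (n_ax + 1) / 2) * geometry$spacing_axial_mm
  dtheta <- geometry$spacing_circ_mm / R
  n_circ <- max(1L, floor(2 * pi / dtheta))
  theta <- (seq_len(n_circ) - (n_circ + 1) / 2) * dtheta
  g <- expand.grid(theta_rad = theta, z_mm = z)
  data.frame(u_mm = R * g$theta_rad, v_mm = g$z_mm,
             theta_rad = g$theta_rad, z_mm = g$z_mm)
}

#' Sample a planned dose grid at the detector diodes
#'
#' Emulates the detector reading a dose distribution, which the synthetic
#' pipeline uses to manufacture "measured" point sets. For a 3D grid the
#' diodes sit on the physical cylinder (axis along the grid z axis, centred
#' in the grid unless `center_mm` is given) and doses are trilinearly
#' interpolated; for a 2D grid the grid is taken to be the already-unwrapped
#' detector plane (`y` = v, `x` = u) and the diode lattice is sampled
#' bilinearly.
#'
#' @param grid a [dose_grid].
#' @param geometry a [detector_geometry].
#' @param center_mm optional cylinder-centre position in grid coordinates
#'   (same axis order as the grid); defaults to the grid centre.
#' @return a [dose_points] in unwrapped coordinates.
#' @export
sample_detector <- function(grid, geometry = detector_geometry(),
                            center_mm = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(geometry, "detector_geometry"))
  ext <- grid_extent(grid)
  nd <- length(dim(grid$values))
  if (is.null(center_mm)) center_mm <- colMeans(ext)
  pos <- detector_positions(geometry)

  if (nd == 3L) {
    R <- geometry$cylinder_radius_mm
    z <- center_mm[1] + pos$z_mm
    y <- center_mm[2] + R * cos(pos$theta_rad)
    x <- center_mm[3] + R * sin(pos$theta_rad)
    check_fit(list(z = z, y = y, x = x), ext, c("z", "y", "x"))
    doses <- interp_trilinear(grid$values, grid$spacing_mm, grid$origin_mm, z, y, x)
  } else {
    y <- center_mm[1] + pos$v_mm
    x <- center_mm[2] + pos$u_mm
    check_fit(list(y = y, x = x), ext, c("y", "x"))
    doses <- interp_bilinear(grid$values, grid$spacing_mm, grid$origin_mm, y, x)
  }
  dose_points(pos$u_mm, pos$v_mm, doses)
}

check_fit <- function(coords, ext, axes) {
  for (i in seq_along(coords)) {
    rng <- range(coords[[i]])
    if (rng[1] < ext[1, i] || rng[2] > ext[2, i]) {
      stop("detector does not fit inside the dose grid along the ", axes[i],
           " axis (needs [", signif(rng[1], 5), ", ", signif(rng[2], 5),
           "] mm, grid covers [", signif(ext[1, i], 5), ", ",
           signif(ext[2, i], 5), "] mm)", call. = FALSE)
    }
  }
  invisible(TRUE)
}
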