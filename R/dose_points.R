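#' Measured detector point doses on the unwrapped cylinder plane
#'
#' The reference distribution scored by the gamma comparison: one dose per
#' diode of a cylindrical array, addressed by unwrapped plane coordinates.
#' `u_mm` is arc length along the circumference (0 at the top of the
#' cylinder, increasing clockwise viewed from the gantry), `v_mm` is the
#' axial position.
#'
#' @param u_mm,v_mm finite coordinates in mm.
#' @param dose_Gy non-negative doses in Gy.
#' @param meta list of measurement metadata; recognised entries are
#'   `detector_id`, `date` and `output_correction` (defaults to 1).
#' @return object of class `dose_points` with a `points` data frame and
#'   `meta` list.
#' @export
dose_points <- function(u_mm, v_mm, dose_Gy, meta = list()) {
  n <- length(dose_Gy)
  if (n == 0L) stop("a dose point set must contain at least one point", call. = FALSE)
  if (length(u_mm) != n || length(v_mm) != n) {
    stop("u_mm, v_mm and dose_Gy must have equal length", call. = FALSE)
  }
  if (any(!is.finite(u_mm)) || any(!is.finite(v_mm))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  if (any(!is.finite(dose_Gy)) || any(dose_Gy < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  if (is.null(meta$output_correction)) meta$output_correction <- 1
  structure(
    list(points = data.frame(u_mm = as.numeric(u_mm), v_mm = as.numeric(v_mm),
                             dose_Gy = as.numeric(dose_Gy)),
         meta = meta),
    class = "dose_points"
  )
}

#' @export
print.dose_points <- function(x, ...) {
  cat("<dose_points> ", nrow(x$points), " points, dose range [",
      signif(min(x$points$dose_Gy), 4), ", ", signif(max(x$points$dose_Gy), 4),
      "] Gy, output correction ", x$meta$output_correction, "\n", sep = "")
  invisible(x)
}

#' Apply a machine output correction to measured doses
#'
#' Before each measurement session the machine output is checked against an
#' ionisation-chamber reference, and the resulting scalar correction is
#' applied to the detector analysis. Corrections compose multiplicatively and
#' the cumulative factor is recorded in the point-set metadata.
#'
#' @param points a [dose_points].
#' @param factor scalar in (0.5, 1.5); the deliberately narrow bound guards
#'   against unit mistakes (a daily output drift is a percent-level effect).
#' @return corrected [dose_points].
#' @examples
#' p <- dose_points(0, 0, 2)
#' apply_output_correction(p, 1.02)$points$dose_Gy
#' @export
apply_output_correction <- function(points, factor) {
  stopifnot(inherits(points, "dose_points"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0.5 || factor >= 1.5) {
    stop("output correction factor must lie strictly within (0.5, 1.5); got ",
         factor, call. = FALSE)
  }
  points$points$dose_Gy <- points$points$dose_Gy * factor
  points$meta$output_correction <- points$meta$output_correction * factor
  points
}

#' Read / write measured point doses (csv-points dialect)
#'
#' Plain CSV with header `u_mm,v_mm,dose_Gy`, one point per line. Metadata is
#' carried in optional leading comment lines of the form `# key: value`.
#'
#' @param path file path.
#' @return a [dose_points].
#' @export
read_dose_points <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L || trimws(body[1]) != "u_mm,v_mm,dose_Gy") {
    stop("csv-points file must start with header 'u_mm,v_mm,dose_Gy'", call. = FALSE)
  }
  df <- utils::read.csv(text = body)
  dose_points(df$u_mm, df$v_mm, df$dose_Gy, meta = meta)
}

#' @rdname read_dose_points
#' @param points a [dose_points] to write.
#' @export
write_dose_points <- function(points, path) {
  stopifnot(inherits(points, "dose_points"))
  meta <- points$meta
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    paste0("# ", k, ": ", if (is.numeric(v)) sprintf("%.10g", v) else as.character(v))
  }, "")
  body <- sprintf("%.6g,%.6g,%.6g", points$points$u_mm, points$points$v_mm,
                  points$points$dose_Gy)
  writeLines(c(hdr, "u_mm,v_mm,dose_Gy", body), path)
  invisible(path)
}
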