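#' Planned dose distribution on a regular grid
#'
#' The evaluation distribution searched during distance-to-agreement
#' minimisation. Axis order is `(y, x)` for 2D grids and `(z, y, x)` for 3D
#' grids; coordinates are millimetres with the origin at the first sample,
#' doses are Gy. Treatment planning exports at high resolution use a
#' 1.87 mm grid step, which is the package-wide default.
#'
#' @param values numeric matrix (2D) or 3D array of doses in Gy; all values
#'   must be finite and non-negative, with at least 2 samples per axis.
#' @param spacing_mm positive grid step per axis (recycled if scalar).
#' @param origin_mm position of the first sample per axis (default 0).
#' @return object of class `dose_grid` with fields `values`, `spacing_mm`,
#'   `origin_mm`.
#' @examples
#' g <- dose_grid(matrix(1:4 / 2, 2, 2), spacing_mm = 1.87)
#' max(g$values)
#' @export
dose_grid <- function(values, spacing_mm = 1.87, origin_mm = NULL) {
  if (!is.numeric(values) || !(length(dim(values)) %in% c(2L, 3L))) {
    stop("`values` must be a numeric matrix (2D) or 3D array", call. = FALSE)
  }
  nd <- length(dim(values))
  if (any(dim(values) < 2L)) {
    stop("dose grid needs at least 2 samples per axis", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  spacing_mm <- rep_len(as.numeric(spacing_mm), nd)
  if (any(spacing_mm <= 0)) stop("spacing must be positive on every axis", call. = FALSE)
  if (is.null(origin_mm)) origin_mm <- rep(0, nd)
  origin_mm <- rep_len(as.numeric(origin_mm), nd)
  if (any(!is.finite(origin_mm))) stop("origin must be finite", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " samples, spacing [", paste(signif(x$spacing_mm, 4), collapse = ", "),
      "] mm, max dose ", signif(max(x$values), 4), " Gy\n", sep = "")
  invisible(x)
}

# Per-axis extent as a 2 x ndim matrix (row 1 = min, row 2 = max), in mm.
grid_extent <- function(grid) {
  d <- dim(grid$values)
  rbind(grid$origin_mm, grid$origin_mm + (d - 1) * grid$spacing_mm)
}

# Interpolate grid dose at continuous positions (mm). `coords` is a matrix
# with one column per axis in grid axis order. NA outside the extent.
grid_interp <- function(grid, coords) {
  coords <- as.matrix(coords)
  if (length(dim(grid$values)) == 2L) {
    interp_bilinear(grid$values, grid$spacing_mm, grid$origin_mm,
                    coords[, 1], coords[, 2])
  } else {
    interp_trilinear(grid$values, grid$spacing_mm, grid$origin_mm,
                     coords[, 1], coords[, 2], coords[, 3])
  }
}

#' Read a planned dose grid
#'
#' Two on-disk formats are supported: `"csv-grid"`, a human-readable dialect
#' with two comment headers (`# spacing_mm: sy sx`, `# origin_mm: oy ox`)
#' followed by comma-separated dose rows, and `"dicom-rtdose"`, a DICOM RT
#' Dose object (explicit VR little endian) whose stored integers are scaled
#' to Gy by the dose-grid-scaling attribute.
#'
#' @param path file to read.
#' @param format `"csv-grid"` or `"dicom-rtdose"`; the default guesses from
#'   the file extension (`.dcm` means DICOM).
#' @return a [dose_grid].
#' @export
read_dose_grid <- function(path, format = c("auto", "csv-grid", "dicom-rtdose")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom-rtdose" else "csv-grid"
  }
  if (format == "dicom-rtdose") return(read_dicom_rtdose(path))
  lines <- readLines(path)
  sp_line <- grep("^#\\s*spacing_mm:", lines, value = TRUE)
  or_line <- grep("^#\\s*origin_mm:", lines, value = TRUE)
  if (length(sp_line) != 1L) {
    stop("csv-grid file is missing the '# spacing_mm:' header", call. = FALSE)
  }
  parse_nums <- function(line) {
    as.numeric(strsplit(trimws(sub("^#[^:]*:", "", line)), "\\s+")[[1]])
  }
  spacing <- parse_nums(sp_line)
  origin <- if (length(or_line) == 1L) parse_nums(or_line) else rep(0, length(spacing))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("csv-grid body has fewer than 2 rows", call. = FALSE)
  rows <- lapply(strsplit(body, ","), function(r) as.numeric(trimws(r)))
  nc <- unique(vapply(rows, length, 1L))
  if (length(nc) != 1L) stop("ragged csv-grid rows", call. = FALSE)
  values <- do.call(rbind, rows)
  dose_grid(values, spacing_mm = spacing, origin_mm = origin)
}

#' Write a planned dose grid
#'
#' @param grid a [dose_grid]. The csv-grid dialect is 2D only; DICOM supports
#'   2D (single frame) and 3D (multi-frame) grids.
#' @param path output file.
#' @param format `"csv-grid"` (doses at 6 significant digits) or
#'   `"dicom-rtdose"`.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path, format = c("csv-grid", "dicom-rtdose")) {
  stopifnot(inherits(grid, "dose_grid"))
  format <- match.arg(format)
  if (format == "dicom-rtdose") return(write_dicom_rtdose(grid, path))
  if (length(dim(grid$values)) != 2L) {
    stop("csv-grid format stores 2D grids only; use dicom-rtdose for 3D",
         call. = FALSE)
  }
  fmt <- function(v) sprintf("%.6g", v)
  lines <- c(
    paste("# spacing_mm:", paste(fmt(grid$spacing_mm), collapse = " ")),
    paste("# origin_mm:", paste(fmt(grid$origin_mm), collapse = " ")),
    apply(grid$values, 1, function(r) paste(fmt(r), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
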