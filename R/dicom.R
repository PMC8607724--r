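# Minimal DICOM RT Dose I/O (explicit VR little endian only).
#
# Supports exactly what a planned-dose export needs: rows/columns/frames,
# pixel spacing, image position, grid frame offsets, dose grid scaling and
# 32-bit unsigned stored doses. Anything else (other transfer syntaxes,
# sequences with undefined length, compressed pixel data) is rejected with a
# clear error rather than guessed at.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
u32 <- function(bytes, at) {
  v <- readBin(bytes[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# VRs carrying a 2-byte reserved field and 4-byte length in explicit VR.
LONG_VRS <- c("OB", "OW", "OF", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_rtdose <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  pos <- 133L
  elems <- list()
  transfer_syntax <- NULL
  while (pos + 7L <= length(bytes)) {
    group <- u16(bytes, pos)
    elem <- u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported transfer syntax (implicit VR?) in ", path, call. = FALSE)
    }
    if (vr %in% LONG_VRS) {
      len <- u32(bytes, pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(bytes, pos + 6L)
      hdr <- 8L
    }
    if (len == 2^32 - 1) {
      stop("undefined-length elements are not supported", call. = FALSE)
    }
    val_at <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    raw_val <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    elems[[key]] <- list(vr = vr, raw = raw_val)
    if (key == "0002,0010") {
      transfer_syntax <- trimws(gsub("\\x00", "", rawToChar(raw_val), useBytes = TRUE))
    }
    pos <- val_at + len
    if (key == "7fe0,0010") break
  }
  if (!is.null(transfer_syntax) && transfer_syntax != TRANSFER_SYNTAX_EXPLICIT_LE) {
    stop("unsupported transfer syntax: ", transfer_syntax, call. = FALSE)
  }

  get_str <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    trimws(gsub("\\x00", "", rawToChar(e$raw), useBytes = TRUE))
  }
  get_nums <- function(key) {
    s <- get_str(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_u16 <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    u16(e$raw, 1L)
  }

  modality <- get_str("0008,0060")
  if (is.null(modality) || modality != "RTDOSE") {
    stop("not an RT Dose object (modality is ",
         if (is.null(modality)) "absent" else shQuote(modality), ")", call. = FALSE)
  }
  rows <- get_u16("0028,0010")
  cols <- get_u16("0028,0011")
  spacing <- get_nums("0028,0030")   # (row, column) = (sy, sx)
  if (is.null(spacing) || length(spacing) != 2L) {
    stop("missing or malformed PixelSpacing (0028,0030)", call. = FALSE)
  }
  ipp <- get_nums("0020,0032")       # (x, y, z) of first voxel
  if (is.null(ipp)) ipp <- c(0, 0, 0)
  n_frames <- get_nums("0028,0008")
  n_frames <- if (is.null(n_frames)) 1L else as.integer(n_frames)
  scaling <- get_nums("3004,000e")
  if (is.null(scaling)) stop("missing DoseGridScaling (3004,000E)", call. = FALSE)
  bits <- get_u16("0028,0100")
  if (is.null(bits) || bits != 32L) {
    stop("only 32-bit stored doses are supported", call. = FALSE)
  }
  px <- elems[["7fe0,0010"]]
  if (is.null(px)) stop("missing PixelData (7FE0,0010)", call. = FALSE)
  n_px <- rows * cols * n_frames
  if (length(px$raw) < 4L * n_px) stop("truncated PixelData", call. = FALSE)
  stored <- readBin(px$raw, "integer", n = n_px, size = 4L, endian = "little")
  stored <- ifelse(stored < 0, stored + 2^32, stored)
  doses <- stored * scaling

  if (n_frames == 1L) {
    # pixel order: row-major within the frame
    values <- matrix(doses, nrow = rows, ncol = cols, byrow = TRUE)
    dose_grid(values, spacing_mm = spacing, origin_mm = c(ipp[2], ipp[1]))
  } else {
    offsets <- get_nums("3004,000c")
    if (is.null(offsets) || length(offsets) != n_frames) {
      stop("missing or malformed GridFrameOffsetVector (3004,000C)", call. = FALSE)
    }
    dz <- unique(round(diff(offsets), 9))
    if (length(dz) != 1L || dz <= 0) {
      stop("non-uniform frame offsets are not supported", call. = FALSE)
    }
    values <- array(0, dim = c(n_frames, rows, cols))
    for (f in seq_len(n_frames)) {
      fr <- doses[((f - 1L) * rows * cols + 1L):(f * rows * cols)]
      values[f, , ] <- matrix(fr, nrow = rows, ncol = cols, byrow = TRUE)
    }
    dose_grid(values, spacing_mm = c(dz, spacing),
              origin_mm = c(ipp[3] + offsets[1], ipp[2], ipp[1]))
  }
}

# --- writer ------------------------------------------------------------

dcm_u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {  # values are padded to even length
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1L
  }
  head <- c(dcm_u16_raw(group), dcm_u16_raw(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), dcm_u32_raw(len), value_raw)
  } else {
    if (len > 65535L) stop("element too long for short VR", call. = FALSE)
    c(head, dcm_u16_raw(len), value_raw)
  }
}

dcm_str_element <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(s))
}
dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

write_dicom_rtdose <- function(grid, path) {
  nd <- length(dim(grid$values))
  if (nd == 2L) {
    n_frames <- 1L
    rows <- nrow(grid$values); cols <- ncol(grid$values)
    sp <- grid$spacing_mm                      # (sy, sx)
    ipp <- c(grid$origin_mm[2], grid$origin_mm[1], 0)
    offsets <- 0
    doses <- as.vector(t(grid$values))         # row-major
  } else {
    d <- dim(grid$values)
    n_frames <- d[1]; rows <- d[2]; cols <- d[3]
    sp <- grid$spacing_mm[2:3]
    ipp <- c(grid$origin_mm[3], grid$origin_mm[2], grid$origin_mm[1])
    offsets <- (seq_len(n_frames) - 1L) * grid$spacing_mm[1]
    doses <- unlist(lapply(seq_len(n_frames),
                           function(f) as.vector(t(grid$values[f, , ]))))
  }
  max_dose <- max(doses)
  scaling <- if (max_dose > 0) max_dose / (2^31 - 1) else 1
  stored <- as.integer(round(doses / scaling))
  pixel_raw <- writeBin(stored, raw(), size = 4L, endian = "little")

  meta <- c(
    dcm_str_element(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    dcm_str_element(0x0002L, 0x0003L, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_str_element(0x0002L, 0x0010L, "UI", TRANSFER_SYNTAX_EXPLICIT_LE)
  )
  meta_len <- dcm_element(0x0002L, 0x0000L, "UL", dcm_u32_raw(length(meta)))

  body <- c(
    dcm_str_element(0x0008L, 0x0060L, "CS", "RTDOSE"),
    dcm_str_element(0x0020L, 0x0032L, "DS", dcm_ds(ipp)),
    dcm_element(0x0028L, 0x0002L, "US", dcm_u16_raw(1L)),
    dcm_str_element(0x0028L, 0x0008L, "IS", as.character(n_frames)),
    dcm_element(0x0028L, 0x0010L, "US", dcm_u16_raw(rows)),
    dcm_element(0x0028L, 0x0011L, "US", dcm_u16_raw(cols)),
    dcm_str_element(0x0028L, 0x0030L, "DS", dcm_ds(sp)),
    dcm_element(0x0028L, 0x0100L, "US", dcm_u16_raw(32L)),
    dcm_element(0x0028L, 0x0101L, "US", dcm_u16_raw(32L)),
    dcm_element(0x0028L, 0x0102L, "US", dcm_u16_raw(31L)),
    dcm_element(0x0028L, 0x0103L, "US", dcm_u16_raw(0L)),
    dcm_str_element(0x3004L, 0x0002L, "CS", "GY"),
    dcm_str_element(0x3004L, 0x000cL, "DS", dcm_ds(offsets)),
    dcm_str_element(0x3004L, 0x000eL, "DS", sprintf("%.16g", scaling)),
    dcm_element(0x7fe0L, 0x0010L, "OW", pixel_raw)
  )
  out <- c(raw(128L), charToRaw("DICM"), meta_len, meta, body)
  writeBin(out, path)
  invisible(path)
}
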