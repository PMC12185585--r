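# Minimal single-frame DICOM support (explicit VR, little endian).
#
# Scope is deliberately narrow: enough to ingest a single-frame grayscale MR
# slice (Rows, Columns, PixelSpacing, BitsAllocated, PixelData) and to write
# such files for round-trip testing. Multi-frame series, compressed transfer
# syntaxes and implicit VR are out of scope.

.dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame grayscale DICOM file
#'
#' Parses explicit-VR little-endian data elements until PixelData. Intensities
#' are returned as stored (no rescale slope/intercept applied).
#'
#' @param path file path.
#' @return list with `pixels` (integer matrix, row-major), `spacing`
#'   (`c(row_mm, col_mm)` or `NULL` when the file has no PixelSpacing),
#'   and `tags` (named list of the string-valued elements encountered).
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  off <- 0L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L

  u16 <- function(i) readBin(raw[(i + 1):(i + 2)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[(i + 1):(i + 4)], "integer", size = 4,
                             endian = "little")

  tags <- list(); rows <- cols <- NULL; spacing <- NULL
  bits_alloc <- 16L; pixel_raw <- NULL
  i <- off
  n <- length(raw)
  while (i + 8 <= n) {
    group <- u16(i); elem <- u16(i + 2)
    vr <- rawToChar(raw[(i + 5):(i + 6)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("not an explicit-VR little-endian DICOM element at byte ", i)
    if (vr %in% .dicom_long_vrs) {
      len <- u32(i + 8); body <- i + 12
    } else {
      len <- u16(i + 6); body <- i + 8
    }
    if (len < 0 || body + len > n) stop("truncated DICOM element")
    val_raw <- raw[(body + 1):(body + len)]
    key <- sprintf("%04x,%04x", group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      pixel_raw <- val_raw
      i <- body + len
      next
    }
    if (vr %in% c("US", "SS")) {
      v <- readBin(val_raw, "integer", n = len / 2, size = 2,
                   endian = "little", signed = (vr == "SS"))
      tags[[key]] <- v
      if (group == 0x0028 && elem == 0x0010) rows <- v[1]
      if (group == 0x0028 && elem == 0x0011) cols <- v[1]
      if (group == 0x0028 && elem == 0x0100) bits_alloc <- v[1]
    } else if (vr %in% c("UL", "SL")) {
      tags[[key]] <- readBin(val_raw, "integer", n = len / 4, size = 4,
                             endian = "little")
    } else {
      v <- sub("[ \\0]+$", "", rawToChar(val_raw))
      tags[[key]] <- v
      if (group == 0x0028 && elem == 0x0030)  # PixelSpacing: "row\col"
        spacing <- as.numeric(strsplit(v, "\\\\")[[1]])[1:2]
    }
    i <- body + len
  }
  if (is.null(pixel_raw)) stop("no PixelData (7fe0,0010) element found")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns attributes")
  if (bits_alloc == 16L) {
    px <- readBin(pixel_raw, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = FALSE)
  } else if (bits_alloc == 8L) {
    px <- as.integer(pixel_raw[seq_len(rows * cols)])
  } else stop("unsupported BitsAllocated: ", bits_alloc)
  list(pixels = matrix(px, nrow = rows, ncol = cols, byrow = TRUE),
       spacing = spacing, tags = tags)
}

#' Write a single-frame grayscale DICOM file
#'
#' Explicit VR little endian; intended for fixtures and round-trip tests.
#'
#' @param pixels integer matrix (values 0..65535).
#' @param path output path.
#' @param spacing optional `c(row_mm, col_mm)` written as PixelSpacing;
#'   omitted from the file when `NULL`.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, spacing = NULL) {
  stopifnot(is.matrix(pixels))
  el <- function(group, elem, vr, val_raw) {
    head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
              writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
              charToRaw(vr))
    if (vr %in% .dicom_long_vrs) {
      c(head, as.raw(c(0, 0)),
        writeBin(length(val_raw), raw(), size = 4, endian = "little"), val_raw)
    } else {
      c(head, writeBin(length(val_raw), raw(), size = 2, endian = "little"),
        val_raw)
    }
  }
  str_val <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
    r
  }
  us_val <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  px <- as.integer(round(t(pixels)))  # row-major stream
  body <- c(
    el(0x0008, 0x0060, "CS", str_val("MR")),
    el(0x0028, 0x0002, "US", us_val(1L)),
    el(0x0028, 0x0010, "US", us_val(nrow(pixels))),
    el(0x0028, 0x0011, "US", us_val(ncol(pixels))),
    if (!is.null(spacing))
      el(0x0028, 0x0030, "DS", str_val(sprintf("%g\\%g", spacing[1], spacing[2]))),
    el(0x0028, 0x0100, "US", us_val(16L)),
    el(0x0028, 0x0101, "US", us_val(16L)),
    el(0x0028, 0x0102, "US", us_val(15L)),
    el(0x0028, 0x0103, "US", us_val(0L)),
    el(0x7FE0, 0x0010, "OW",
       writeBin(px, raw(), size = 2, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(rep(0, 128)), charToRaw("DICM"), body), con)
  invisible(path)
}
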