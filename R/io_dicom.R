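# Minimal DICOM support for 8-bit greyscale ultrasound exports.
#
# Scope: uncompressed little-endian transfer syntaxes (implicit VR
# 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1), BitsAllocated = 8,
# MONOCHROME1/MONOCHROME2 or interleaved RGB, single- or multi-frame.
# This covers the B-mode clip exports the texture method consumes; anything
# else (compressed pixel data, >8-bit depth, undefined-length sequences)
# raises an unsupported-format error rather than guessing.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs that use the 2-byte-reserved + 4-byte-length layout in explicit VR.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
uint32le <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

read_dicom_elements <- function(bytes) {
  n <- length(bytes)
  if (n < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic)", call. = FALSE)
  pos <- 133L
  elems <- list()
  explicit <- TRUE  # file meta group is always explicit little endian
  ts <- TS_EXPLICIT_LE
  meta_done <- FALSE
  while (pos + 7L <= n) {
    group <- uint16le(bytes[pos:(pos + 1L)])
    elem  <- uint16le(bytes[(pos + 2L):(pos + 3L)])
    if (!meta_done && group != 0x0002) {
      meta_done <- TRUE
      explicit <- identical(ts, TS_EXPLICIT_LE)
      if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- uint32le(bytes[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- uint16le(bytes[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- uint32le(bytes[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295) # 0xFFFFFFFF undefined length
      stop("unsupported DICOM element with undefined length (compressed or sequence data)",
           call. = FALSE)
    start <- pos + hdr
    if (start + len - 1L > n)
      stop("truncated DICOM file", call. = FALSE)
    val <- if (len > 0) bytes[start:(start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    elems[[key]] <- list(vr = vr, value = val)
    if (key == "0002,0010") ts <- raw_to_string(val)
    if (key == "7FE0,0010") break  # pixel data is last thing we need
    pos <- start + len
  }
  elems
}

raw_to_string <- function(val) trimws(rawToChar(val[val != as.raw(0)]))

elem_string <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  raw_to_string(e$value)
}

elem_uint16 <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  uint16le(e$value[1:2])
}

read_dicom_grey <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  elems <- read_dicom_elements(bytes)
  rows <- elem_uint16(elems, "0028,0010")
  cols <- elem_uint16(elems, "0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns", call. = FALSE)
  bits <- elem_uint16(elems, "0028,0100", 8L)
  if (bits != 8L)
    stop("unsupported pixel depth (", bits,
         " bits allocated, no rescale information): only 8-bit data is supported",
         call. = FALSE)
  spp <- elem_uint16(elems, "0028,0002", 1L)
  photometric <- elem_string(elems, "0028,0004", "MONOCHROME2")
  nframes <- as.integer(elem_string(elems, "0028,0008", "1"))
  if (is.na(nframes) || nframes < 1L) nframes <- 1L
  pd <- elems[["7FE0,0010"]]
  if (is.null(pd)) stop("DICOM file lacks PixelData", call. = FALSE)
  expected <- rows * cols * spp * nframes
  if (length(pd$value) < expected)
    stop("truncated PixelData", call. = FALSE)
  vals <- as.integer(pd$value[seq_len(expected)])
  frames <- vector("list", nframes)
  per_frame <- rows * cols * spp
  for (k in seq_len(nframes)) {
    fv <- vals[((k - 1L) * per_frame + 1L):(k * per_frame)]
    if (spp == 1L) {
      px <- matrix(fv, nrow = rows, ncol = cols, byrow = TRUE)
    } else if (spp == 3L) {
      # interleaved RGB (PlanarConfiguration 0)
      rgb <- matrix(fv, ncol = 3L, byrow = TRUE)
      g <- to_luma(rgb[, 1], rgb[, 2], rgb[, 3])
      px <- matrix(g, nrow = rows, ncol = cols, byrow = TRUE)
    } else {
      stop("unsupported SamplesPerPixel: ", spp, call. = FALSE)
    }
    if (identical(photometric, "MONOCHROME1")) px <- 255L - px
    frames[[k]] <- px
  }
  frames
}

# ITU-R BT.601 luma, rounded to the nearest integer grey level.
to_luma <- function(r, g, b) {
  y <- as.integer(round(0.299 * r + 0.587 * g + 0.114 * b))
  if (min(y) < 0L || max(y) > 255L)
    stop("grey conversion produced values outside [0, 255]", call. = FALSE)
  y
}

put_uint16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
put_uint32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dicom_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {  # DICOM values are even-length
    pad <- if (vr %in% c("UI", "CS", "IS", "LO", "SH")) as.raw(0L) else as.raw(32L)
    if (vr == "OB") pad <- as.raw(0L)
    value_raw <- c(value_raw, pad)
    len <- len + 1L
  }
  hdr <- c(put_uint16le(group), put_uint16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), put_uint32le(len), value_raw)
  } else {
    c(hdr, put_uint16le(len), value_raw)
  }
}

str_el <- function(group, elem, vr, s) dicom_element(group, elem, vr, charToRaw(s))
us_el  <- function(group, elem, x) dicom_element(group, elem, "US", put_uint16le(x))

#' Write frames as a minimal 8-bit greyscale DICOM file
#'
#' Writes one or more 8-bit grey frames as an uncompressed explicit-VR
#' little-endian secondary-capture DICOM file (MONOCHROME2). Used to build
#' reproducible test clips and phantom fixtures; real acquisitions come from
#' the scanner.
#'
#' @param frames a `grey_frame` or list of them, all the same size.
#' @param path output file path.
#' @param photometric `"MONOCHROME2"` (default) or `"MONOCHROME1"` (pixel
#'   values are stored inverted so that the displayed image is unchanged).
#' @return `path`, invisibly.
#' @export
write_dicom_grey <- function(frames, path, photometric = "MONOCHROME2") {
  if (is_grey_frame(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share one size", call. = FALSE)
  rows <- dims[1, 1]; cols <- dims[2, 1]
  photometric <- match.arg(photometric, c("MONOCHROME2", "MONOCHROME1"))
  pix <- unlist(lapply(frames, function(f) {
    m <- unclass(f)
    if (photometric == "MONOCHROME1") m <- 255L - m
    as.integer(t(m))  # row-major pixel order
  }))
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture
  sop_inst <- "1.2.826.0.1.3680043.9999.1"
  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    str_el(0x0002, 0x0002, "UI", sop_class),
    str_el(0x0002, 0x0003, "UI", sop_inst),
    str_el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
  )
  body <- c(
    str_el(0x0008, 0x0016, "UI", sop_class),
    str_el(0x0008, 0x0018, "UI", sop_inst),
    us_el(0x0028, 0x0002, 1L),
    str_el(0x0028, 0x0004, "CS", photometric),
    str_el(0x0028, 0x0008, "IS", as.character(length(frames))),
    us_el(0x0028, 0x0010, rows),
    us_el(0x0028, 0x0011, cols),
    us_el(0x0028, 0x0100, 8L),
    us_el(0x0028, 0x0101, 8L),
    us_el(0x0028, 0x0102, 7L),
    us_el(0x0028, 0x0103, 0L),
    dicom_element(0x7FE0, 0x0010, "OB", as.raw(pix))
  )
  out <- c(raw(128), charToRaw("DICM"),
           dicom_element(0x0002, 0x0000, "UL", put_uint32le(length(meta))),
           meta, body)
  writeBin(out, path)
  invisible(path)
}
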