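#' Read ultrasound frames from DICOM, PNG or TIFF
#'
#' Reads one or all frames of an image file into [grey_frame()] objects.
#' Colour images are converted to grey with the standard BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded to integer levels. DICOM
#' MONOCHROME1 data are inverted to MONOCHROME2 semantics (higher = brighter)
#' before analysis, since all texture features assume brightness-increasing
#' levels.
#'
#' @param path path to a DICOM (single- or multi-frame, 8-bit), PNG or TIFF
#'   file. The format is detected from the file content (DICM magic) and
#'   extension.
#' @param frame_index optional 1-based frame index (or vector of indices)
#'   selecting frames from a multi-frame clip; `NULL` (default) returns all.
#' @return A list of `grey_frame` objects, one per requested frame, with
#'   `source_id` of the form `"<file>#<frame>"`.
#' @export
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), p)
#' f <- read_frames(p)[[1]]
read_frames <- function(path, frame_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  frames <- if (is_dicom_file(path)) {
    read_dicom_grey(path)
  } else {
    ext <- tolower(tools::file_ext(path))
    arr <- switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format: ", path, call. = FALSE))
    list(array_to_grey(arr, path))
  }
  if (!is.null(frame_index)) {
    if (any(frame_index < 1L) || any(frame_index > length(frames)))
      stop("frame_index out of range: file has ", length(frames), " frame(s)",
           call. = FALSE)
    frames <- frames[frame_index]
    idx <- frame_index
  } else {
    idx <- seq_along(frames)
  }
  mapply(function(px, k) grey_frame(px, sprintf("%s#%d", basename(path), k)),
         frames, idx, SIMPLIFY = FALSE)
}

is_dicom_file <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("dcm", "dicom")) return(TRUE)
  if (file.size(path) < 132) return(FALSE)
  bytes <- readBin(path, "raw", n = 132)
  length(bytes) == 132 && identical(bytes[129:132], charToRaw("DICM"))
}

# PNG/TIFF readers return numeric arrays in [0,1]; recover 8-bit integers.
array_to_grey <- function(arr, path) {
  if (is.list(arr)) arr <- arr[[1]]  # multi-image TIFF: first directory
  x <- round(arr * 255)
  if (length(dim(x)) == 3) {
    nc <- dim(x)[3]
    if (nc >= 3) {
      g <- to_luma(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
      x <- matrix(g, dim(x)[1], dim(x)[2])
    } else {
      x <- x[, , 1]  # grey (+ alpha ignored)
    }
  }
  if (min(x) < 0 || max(x) > 255)
    stop("pixel values outside [0, 255] after conversion: ", path, call. = FALSE)
  x
}

#' Write a per-zone feature table to CSV
#'
#' One row per (subject, zone) record, one column per texture feature,
#' written with enough precision that a round-trip read agrees to at least
#' 12 significant digits.
#'
#' @param records data.frame with columns `subject_id`, `zone_id` and one
#'   numeric column per feature, or a list of records as produced by the
#'   extraction pipeline.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  df <- as_feature_df(records)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with `subject_id`, `zone_id` as character and features
#'   numeric.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("subject_id", "zone_id", "group"), names(df)))
    df[[nm]] <- as.character(df[[nm]])
  df
}

as_feature_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (!is.list(records)) stop("records must be a data.frame or list", call. = FALSE)
  if (length(records) == 0)
    return(data.frame(subject_id = character(0), zone_id = character(0)))
  rows <- lapply(records, function(r) {
    fv <- r$features
    data.frame(subject_id = r$subject_id, zone_id = r$zone_id,
               as.list(unclass(fv)), stringsAsFactors = FALSE)
  })
  fnames <- lapply(rows, names)
  if (length(unique(vapply(fnames, paste, character(1), collapse = ","))) != 1)
    stop("records do not share a common feature-name set", call. = FALSE)
  do.call(rbind, rows)
}
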