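#' Grey-scale ultrasound frame
#'
#' A `grey_frame` is the raw unit of analysis: a 2-D integer matrix of
#' grey levels in \[0, 255\], row-major with the origin at the top-left and
#' (row, column) indexing. Ultrasound B-mode exports analysed by this
#' package are 8-bit, so 255 is full white.
#'
#' @param pixels integer matrix of grey levels in \[0, 255\], at least 2 x 2.
#' @param source_id character label identifying the file (and frame index)
#'   the pixels came from.
#'
#' @return An object of class `grey_frame`: the integer pixel matrix with a
#'   `source_id` attribute.
#' @export
#' @examples
#' f <- grey_frame(matrix(0:255, 16, 16), "ramp")
#' dim(f)
grey_frame <- function(pixels, source_id = "frame") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("frame must be at least 2 x 2 pixels", call. = FALSE)
  if (anyNA(pixels)) stop("frame contains missing pixel values", call. = FALSE)
  px <- pixels
  if (!is.integer(px)) {
    if (any(abs(px - round(px)) > 1e-9))
      stop("pixel values must be integers", call. = FALSE)
    px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  }
  if (min(px) < 0L || max(px) > 255L)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(px, source_id = as.character(source_id), class = c("grey_frame", "matrix"))
}

#' @export
print.grey_frame <- function(x, ...) {
  cat(sprintf("<grey_frame> %d x %d, grey range [%d, %d], source: %s\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "source_id")))
  invisible(x)
}

is_grey_frame <- function(x) inherits(x, "grey_frame")

# The 12 standard chest zones: anterior/lateral/posterior x upper/lower x
# left/right hemithorax.
#' Standard lung-ultrasound zone labels
#'
#' The twelve standard chest areas (anterior, lateral, posterior; each upper
#' and lower; both hemithoraces) scanned per subject.
#'
#' @return Character vector of the 12 zone labels.
#' @export
zone_labels <- function() {
  as.vector(outer(
    outer(c("anterior", "lateral", "posterior"), c("upper", "lower"), paste, sep = "_"),
    c("left", "right"), paste, sep = "_"))
}
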