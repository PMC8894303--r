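#' Regions of interest around the pleural line
#'
#' In clinical use the operator outlines the pleural line either with a
#' rectangle or, to follow the line's course and exclude rib shadows, with a
#' polygon. Vertices are 0-based (row, column) pixel coordinates; the frame
#' origin is the top-left pixel and rows increase downwards.
#'
#' @param kind `"rectangle"` or `"polygon"`.
#' @param vertices numeric matrix (or list of length-2 vectors) of (row, col)
#'   coordinates: exactly two opposite corners for a rectangle, at least
#'   three vertices for a polygon.
#' @return An object of class `roi_shape`.
#' @export
#' @examples
#' roi_shape("rectangle", rbind(c(0, 0), c(9, 19)))
roi_shape <- function(kind = c("rectangle", "polygon"), vertices) {
  kind <- match.arg(kind)
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must be (row, col) pairs", call. = FALSE)
  if (kind == "rectangle" && nrow(vertices) != 2)
    stop("a rectangle takes exactly 2 opposite corners", call. = FALSE)
  if (kind == "polygon" && nrow(vertices) < 3)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  structure(list(kind = kind, vertices = unname(vertices)), class = "roi_shape")
}

#' @export
print.roi_shape <- function(x, ...) {
  cat(sprintf("<roi_shape> %s with %d vertices\n", x$kind, nrow(x$vertices)))
  invisible(x)
}

#' Rasterize an ROI shape to a boolean pixel mask
#'
#' Rectangles include every pixel whose row and column lie in the closed
#' interval between the two corners. Polygons use the even-odd interior rule
#' tested at pixel centers, with pixels on the boundary counted inside.
#' Non-convex polygons are allowed.
#'
#' @param shape an [roi_shape()].
#' @param height,width frame dimensions in pixels.
#' @return An object of class `roi_mask`: a `height` x `width` logical matrix
#'   with attribute `n_inside`.
#' @export
rasterize <- function(shape, height, width) {
  stopifnot(inherits(shape, "roi_shape"))
  v <- shape$vertices
  if (min(v) < 0 || max(v[, 1]) > height - 1 || max(v[, 2]) > width - 1)
    stop("ROI vertices fall outside the frame bounds", call. = FALSE)
  mask <- matrix(FALSE, height, width)
  if (shape$kind == "rectangle") {
    r <- sort(v[, 1]); c <- sort(v[, 2])
    mask[(floor(r[1]):ceiling(r[2])) + 1L, (floor(c[1]):ceiling(c[2])) + 1L] <- TRUE
  } else {
    if (polygon_area(v) == 0)
      stop("degenerate polygon with zero area", call. = FALSE)
    rows <- matrix(rep(0:(height - 1), width), height, width)
    cols <- matrix(rep(0:(width - 1), each = height), height, width)
    mask[] <- points_in_polygon(as.vector(rows), as.vector(cols), v)
  }
  n_inside <- sum(mask)
  if (n_inside < 2)
    stop("ROI mask covers fewer than 2 pixels; no pixel pair can be formed",
         call. = FALSE)
  structure(mask, n_inside = n_inside, class = c("roi_mask", "matrix"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, %d pixels inside\n",
              nrow(x), ncol(x), attr(x, "n_inside")))
  invisible(x)
}

#' Full-frame ROI mask
#' @param height,width frame dimensions in pixels.
#' @return An `roi_mask` covering every pixel.
#' @export
full_mask <- function(height, width) {
  structure(matrix(TRUE, height, width), n_inside = height * width,
            class = c("roi_mask", "matrix"))
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Even-odd point-in-polygon at pixel centers, boundary counted inside.
# Vectorized over query points; px/py are the point rows/cols.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    r1 <- v[j, 1]; c1 <- v[j, 2]; r2 <- v[i, 1]; c2 <- v[i, 2]
    # boundary test: point collinear with the segment and within its bbox
    cross <- (c2 - c1) * (px - r1) - (r2 - r1) * (py - c1)
    on_seg <- abs(cross) < 1e-9 &
      px >= pmin(r1, r2) - 1e-9 & px <= pmax(r1, r2) + 1e-9 &
      py >= pmin(c1, c2) - 1e-9 & py <= pmax(c1, c2) + 1e-9
    on_edge <- on_edge | on_seg
    # even-odd ray cast: horizontal ray in +col direction, crossing test on rows
    crosses <- ((r1 > px) != (r2 > px)) &
      (py < (c2 - c1) * (px - r1) / (r2 - r1) + c1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
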