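#' GLCM computation settings
#'
#' Defaults follow the protocol used for pleural-line analysis: 16 grey
#' levels (a good balance between computation time and preservation of image
#' information), pair distances 1-4 pixels, and all four directions
#' (0, 45, 90, 135 degrees). `averaging` controls how a frame's single
#' feature vector is formed: `"feature"` (default) computes features for each
#' (distance, angle) matrix and averages the feature values; `"matrix"`
#' averages the four directional matrices per distance into a
#' direction-invariant matrix first, computes features per distance, then
#' averages over distances.
#'
#' @param n_levels number of grey levels Ng after quantization, in \[2, 256\].
#' @param distances integer vector of pixel-pair distances, all >= 1.
#' @param angles subset of `c(0, 45, 90, 135)` (degrees), no duplicates.
#' @param averaging `"feature"` or `"matrix"`.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 16, distances = 1:4,
                        angles = c(0, 45, 90, 135),
                        averaging = c("feature", "matrix")) {
  if (n_levels < 2 || n_levels > 256) stop("n_levels must be in [2, 256]", call. = FALSE)
  if (length(distances) < 1 || any(distances < 1))
    stop("distances must all be >= 1", call. = FALSE)
  if (length(angles) < 1 || anyDuplicated(angles) ||
      !all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a non-empty duplicate-free subset of {0, 45, 90, 135}",
         call. = FALSE)
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances),
                 angles = as.numeric(angles),
                 averaging = match.arg(averaging)),
            class = "glcm_config")
}

#' @export
print.glcm_config <- function(x, ...) {
  cat(sprintf("<glcm_config> Ng=%d, d={%s}, angles={%s}, %s averaging\n",
              x$n_levels, paste(x$distances, collapse = ","),
              paste(x$angles, collapse = ","), x$averaging))
  invisible(x)
}

# Displacement (delta_row, delta_col) for an angle, 0-based rows increasing
# downward: 0 deg -> (0, d); 45 -> (-d, d); 90 -> (-d, 0); 135 -> (-d, -d).
# Symmetric accumulation makes the sign convention observationally irrelevant.
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Quantize grey levels
#'
#' Uniform quantization of the fixed 0-255 range into `n_levels` bins:
#' `level = floor(grey * n_levels / 256)`. The range is fixed, not
#' min-max per image, so that level units are comparable across images and
#' subjects.
#'
#' @param frame a [grey_frame()] (or integer matrix of grey values 0-255).
#' @param n_levels number of grey levels Ng in \[2, 256\].
#' @return An object of class `quantized_frame`: integer matrix of levels in
#'   \[0, Ng-1\] with attribute `n_levels`.
#' @export
#' @examples
#' q <- quantize(grey_frame(matrix(c(0, 15, 16, 255), 2, 2)), 16)
#' range(q)  # 0 .. 15
quantize <- function(frame, n_levels = 16) {
  if (n_levels < 2 || n_levels > 256) stop("n_levels must be in [2, 256]", call. = FALSE)
  px <- unclass(frame)
  lv <- matrix(as.integer(floor(px * as.numeric(n_levels) / 256)),
               nrow(px), ncol(px))
  structure(lv, n_levels = as.integer(n_levels),
            class = c("quantized_frame", "matrix"))
}

#' Compute one masked, normalized, symmetric GLCM
#'
#' Counts every ordered pixel pair `(a, a + offset)` with both pixels inside
#' the mask, accumulating symmetrically into (i, j) and (j, i), then
#' normalizes by the realized pair count. The realized count is mask- and
#' border-aware (irregular polygonal ROIs do not have a nominal pair count).
#'
#' @param q a [quantize()]d frame.
#' @param mask an [roi_mask()] of the same shape (default: full frame).
#' @param d pair distance in pixels.
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @return An object of class `glcm`: an Ng x Ng probability matrix with
#'   attributes `d`, `angle`, `n_pairs`.
#' @export
compute_glcm <- function(q, mask = NULL, d = 1, angle = 0) {
  stopifnot(inherits(q, "quantized_frame"))
  ng <- attr(q, "n_levels")
  nr <- nrow(q); nc <- ncol(q)
  if (is.null(mask)) mask <- full_mask(nr, nc)
  if (!all(dim(mask) == c(nr, nc)))
    stop("mask shape must equal frame shape", call. = FALSE)
  off <- glcm_offset(angle, as.integer(d))
  dr <- off[1]; dc <- off[2]
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi)
    stop("no valid pixel pairs inside the ROI for this offset", call. = FALSE)
  rs <- rlo:rhi
  cs <- clo:chi
  a <- unclass(q)[rs, cs, drop = FALSE]
  b <- unclass(q)[rs + dr, cs + dc, drop = FALSE]
  ok <- unclass(mask)[rs, cs, drop = FALSE] &
        unclass(mask)[rs + dr, cs + dc, drop = FALSE]
  if (!any(ok))
    stop("no valid pixel pairs inside the ROI for this offset", call. = FALSE)
  idx <- a[ok] + ng * b[ok] + 1L   # column-major (i+1, j+1)
  counts <- matrix(tabulate(idx, ng * ng), ng, ng)
  counts <- counts + t(counts)     # symmetric accumulation
  n_pairs <- sum(counts)
  structure(counts / n_pairs, d = as.integer(d), angle = angle,
            n_pairs = n_pairs, n_levels = ng, class = c("glcm", "matrix"))
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> Ng=%d, d=%s, angle=%s, %d ordered pairs\n",
              attr(x, "n_levels"), attr(x, "d"),
              as.character(attr(x, "angle")), attr(x, "n_pairs")))
  invisible(x)
}

#' Average co-occurrence matrices entrywise
#'
#' The entrywise arithmetic mean of normalized symmetric GLCMs is itself a
#' normalized symmetric GLCM; averaging over the four directions yields a
#' direction-invariant matrix.
#'
#' @param matrices a list of `glcm` objects sharing one Ng.
#' @return A `glcm` tagged `angle = "averaged"`; `n_pairs` is the total over
#'   the inputs.
#' @export
average_glcms <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0)
    stop("need a non-empty list of glcm matrices", call. = FALSE)
  ngs <- vapply(matrices, function(m) attr(m, "n_levels"), integer(1))
  if (length(unique(ngs)) != 1)
    stop("matrices must share the same number of grey levels", call. = FALSE)
  p <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(p, d = attr(matrices[[1]], "d"), angle = "averaged",
            n_pairs = sum(vapply(matrices, function(m) attr(m, "n_pairs"), numeric(1))),
            n_levels = ngs[1], class = c("glcm", "matrix"))
}
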