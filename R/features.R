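#' Names of the texture features computed from one GLCM
#'
#' The eleven reported second-order features plus cluster prominence, in the
#' fixed output order used by feature tables.
#'
#' @return Character vector of 12 feature names.
#' @export
feature_names <- function() {
  c("contrast", "cluster_shade", "cluster_prominence", "entropy", "variance",
    "mean", "correlation", "energy", "homogeneity", "mean_sum", "entropy_sum",
    "variance_sum")
}

#' Haralick-style texture features of a normalized symmetric GLCM
#'
#' With `p(i, j)` over quantized levels `0..Ng-1`, marginals `px`, `py`
#' (equal for a symmetric matrix) with means `mu_x`, `mu_y` and standard
#' deviations `sigma_x`, `sigma_y`, and the level-sum distribution
#' `p_sum(k) = sum over i+j=k of p(i, j)`:
#'
#' \itemize{
#'   \item contrast: sum (i-j)^2 p — local variation
#'   \item cluster_shade: sum (i+j-mu_x-mu_y)^3 p — skewness; positive for
#'     bright clusters on a darker background, negative for the reverse
#'   \item cluster_prominence: sum (i+j-mu_x-mu_y)^4 p
#'   \item entropy: -sum p log2 p (bits; 0 log 0 := 0)
#'   \item variance: sum (i-mu_x)^2 p — grey-level variability of pixel pairs
#'   \item mean: (mu_x + mu_y) / 2 — mean level of the marginals
#'   \item correlation: sum (i-mu_x)(j-mu_y) p / (sigma_x sigma_y); undefined
#'     (NA) for a constant ROI (sigma_x = 0)
#'   \item energy: sum p^2 (angular second moment)
#'   \item homogeneity: sum p / (1 + (i-j)^2) (inverse difference moment)
#'   \item mean_sum, entropy_sum, variance_sum: mean, entropy (bits) and
#'     variance (about mean_sum) of `p_sum`
#' }
#'
#' All values are in quantized-level units (not rescaled to 0-255).
#'
#' @param m a `glcm` from [compute_glcm()] or [average_glcms()].
#' @return An object of class `texture_features`: a named numeric vector over
#'   [feature_names()].
#' @export
#' @examples
#' q <- quantize(grey_frame(matrix(c(0, 0, 255, 255), 2, 2)), 16)
#' compute_features(compute_glcm(q, d = 1, angle = 90))
compute_features <- function(m) {
  p <- unclass(m)
  ng <- nrow(p)
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop("input is not a normalized co-occurrence matrix", call. = FALSE)
  if (max(abs(p - t(p))) > 1e-12)
    stop("input matrix is not symmetric", call. = FALSE)
  lv <- 0:(ng - 1)
  i <- matrix(lv, ng, ng)        # row level index
  j <- t(i)                      # column level index
  px <- rowSums(p)
  mu_x <- sum(lv * px)
  sigma_x <- sqrt(sum((lv - mu_x)^2 * px))
  mu_y <- mu_x; sigma_y <- sigma_x  # symmetry: marginals coincide

  # level-sum distribution over k = 0 .. 2(Ng-1)
  k <- as.vector(i + j)
  p_sum <- as.vector(tapply(as.vector(p), factor(k, levels = 0:(2 * ng - 2)), sum))
  p_sum[is.na(p_sum)] <- 0
  ks <- 0:(2 * ng - 2)
  mean_sum <- sum(ks * p_sum)

  corr <- if (sigma_x > 0) {
    sum((i - mu_x) * (j - mu_y) * p) / (sigma_x * sigma_y)
  } else NA_real_

  out <- c(
    contrast = sum((i - j)^2 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
    variance = sum((i - mu_x)^2 * p),
    mean = (mu_x + mu_y) / 2,
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    mean_sum = mean_sum,
    entropy_sum = -sum(ifelse(p_sum > 0, p_sum * log2(p_sum), 0)),
    variance_sum = sum((ks - mean_sum)^2 * p_sum)
  )
  structure(out, class = "texture_features")
}

#' @export
print.texture_features <- function(x, digits = 4, ...) {
  cat("<texture_features>\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Marginal statistics of a GLCM
#'
#' Mean and standard deviation of the row and column marginals of a
#' normalized GLCM, in quantized-level units. For a symmetric matrix the row
#' and column values coincide. Exposed for completeness; these quantities
#' feed [compute_features()] but are not part of the 11-feature analysis set.
#'
#' @param m a `glcm`.
#' @return Named list with `mu_x`, `mu_y`, `sigma_x`, `sigma_y`.
#' @export
marginal_stats <- function(m) {
  p <- unclass(m)
  ng <- nrow(p)
  lv <- 0:(ng - 1)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lv * px); mu_y <- sum(lv * py)
  list(mu_x = mu_x, mu_y = mu_y,
       sigma_x = sqrt(sum((lv - mu_x)^2 * px)),
       sigma_y = sqrt(sum((lv - mu_y)^2 * py)))
}
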