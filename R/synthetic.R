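# Synthetic data: texture phantoms of the three pleural-line appearance
# classes, and a Gaussian per-group feature simulator parameterized by the
# published group means/SDs. These stand in for patient images, which are not
# publicly deposited.

#' Phantom specification
#'
#' Describes a synthetic pleural-line texture phantom. The three classes
#' emulate the qualitative appearances of the pleural region:
#' `"healthy"` — sparse bright blobs against a darker, speckled mid-grey
#' background; `"cpe"` — darker blobs against a lighter speckled background
#' (cardiogenic edema); `"ards"` — large connected patches of uniform dark
#' grey within a lighter speckled background. Speckle is a multiplicative
#' unit-mean Rayleigh-like factor blended with weight `speckle_weight`, a
#' minimal ultrasound speckle surrogate. Only sign and ordering claims are
#' made on phantom features, not magnitudes.
#'
#' @param class_label `"healthy"`, `"cpe"` or `"ards"`.
#' @param size integer (height, width) in pixels.
#' @param seed integer seed; phantom generation is pure in (spec, seed).
#' @param background_level,feature_level mean grey levels (0-255) of the
#'   background and of the blobs/patches; defaults depend on the class.
#' @param blob_density fraction of the frame area covered by blobs
#'   (healthy/cpe classes), in (0, 1).
#' @param blob_radius blob radius in pixels; must be < min(size)/2.
#' @param smoothing_scale Gaussian smoothing scale (pixels) of the random
#'   field whose thresholding forms the ARDS patches.
#' @param speckle_weight blend weight of the multiplicative speckle in
#'   \[0, 1\].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("healthy", "cpe", "ards"),
                         size = c(96, 96), seed = 1,
                         background_level = NULL, feature_level = NULL,
                         blob_density = 0.10, blob_radius = 3,
                         smoothing_scale = 8, speckle_weight = 0.3) {
  class_label <- match.arg(class_label)
  defaults <- switch(class_label,
    healthy = c(bg = 140, fg = 235),
    cpe     = c(bg = 185, fg = 90),
    ards    = c(bg = 170, fg = 85))
  if (is.null(background_level)) background_level <- defaults[["bg"]]
  if (is.null(feature_level)) feature_level <- defaults[["fg"]]
  if (background_level < 0 || background_level > 255 ||
      feature_level < 0 || feature_level > 255)
    stop("grey levels must lie in [0, 255]", call. = FALSE)
  if (blob_density <= 0 || blob_density >= 1)
    stop("blob_density must be in (0, 1)", call. = FALSE)
  if (blob_radius >= min(size) / 2)
    stop("blob_radius must be smaller than half the frame", call. = FALSE)
  structure(list(class_label = class_label, size = as.integer(size),
                 seed = as.integer(seed),
                 background_level = background_level,
                 feature_level = feature_level,
                 blob_density = blob_density, blob_radius = blob_radius,
                 smoothing_scale = smoothing_scale,
                 speckle_weight = speckle_weight),
            class = "phantom_spec")
}

#' Generate a texture phantom
#'
#' Deterministic in the spec (including its seed): the same spec always
#' yields the same image.
#'
#' @param spec a [phantom_spec()].
#' @return A [grey_frame()] of the requested size.
#' @export
#' @examples
#' f <- generate_phantom(phantom_spec("healthy", seed = 7))
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  scene <- matrix(spec$background_level, h, w)
  if (spec$class_label %in% c("healthy", "cpe")) {
    n_blobs <- max(1L, round(spec$blob_density * h * w /
                               (pi * spec$blob_radius^2)))
    cr <- stats::runif(n_blobs, 1, h)
    cc <- stats::runif(n_blobs, 1, w)
    rows <- matrix(rep(seq_len(h), w), h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    inside <- matrix(FALSE, h, w)
    for (b in seq_len(n_blobs)) {
      inside <- inside |
        ((rows - cr[b])^2 + (cols - cc[b])^2 <= spec$blob_radius^2)
    }
    scene[inside] <- spec$feature_level
    img <- scene * speckle_field(h, w, spec$speckle_weight)
  } else {
    field <- smooth_field(h, w, spec$smoothing_scale)
    patches <- field < stats::quantile(field, 0.40)  # ~40% patch coverage
    img <- scene * speckle_field(h, w, spec$speckle_weight)
    img[patches] <- spec$feature_level  # uniform dark-grey patches
  }
  px <- pmin(255L, pmax(0L, as.integer(round(img))))
  grey_frame(matrix(px, h, w),
             sprintf("phantom:%s:seed%d", spec$class_label, spec$seed))
}

# Unit-mean Rayleigh-like multiplicative speckle, blended with weight w.
speckle_field <- function(h, w, weight) {
  sigma <- 1 / sqrt(pi / 2)                 # Rayleigh scale with mean 1
  r <- sigma * sqrt(-2 * log(stats::runif(h * w)))
  matrix((1 - weight) + weight * r, h, w)
}

# Gaussian-smoothed white-noise field (separable circular convolution).
smooth_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  half <- max(1L, min(ceiling(3 * scale), floor((min(h, w) - 1) / 2)))
  kern <- stats::dnorm(-half:half, sd = scale)
  kern <- kern / sum(kern)
  conv_circ <- function(x, k) {
    n <- length(x); half <- (length(k) - 1L) / 2L
    xx <- c(x[(n - half + 1L):n], x, x[1:half])
    stats::filter(xx, k, sides = 2)[(half + 1L):(half + n)]
  }
  z <- apply(z, 2, conv_circ, k = kern)
  t(apply(t(z), 2, conv_circ, k = kern))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Published per-group feature distribution parameters
#'
#' Loads the packaged table of per-feature, per-group means and standard
#' deviations (ARDS n = 8, CPE n = 16 subjects) that parameterize the
#' Gaussian feature simulator, or a user-supplied YAML file of the same
#' structure.
#'
#' @param path YAML file; default: the packaged parameter set.
#' @return List with `groups` (group sizes) and `features` (per-feature,
#'   per-group `mean` and `sd`).
#' @export
group_feature_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "group_feature_params.yaml",
                        package = "pleuratex", mustWork = TRUE)
  prm <- yaml::read_yaml(path)
  for (f in names(prm$features))
    for (g in names(prm$features[[f]]))
      if (prm$features[[f]][[g]]$sd <= 0)
        stop("all SDs must be positive (", f, ", ", g, ")", call. = FALSE)
  prm
}

# theoretical bounds used to clip simulated draws
feature_bounds <- function(feature) {
  switch(feature,
    correlation = c(-1, 1),
    energy = c(1e-12, 1),
    homogeneity = c(1e-12, 1),
    contrast = , variance = , variance_sum = , entropy = , entropy_sum = ,
    mean = , mean_sum = , cluster_prominence = c(0, Inf),
    c(-Inf, Inf))
}

#' Simulate per-subject feature values for two groups
#'
#' Independent Gaussian draws per group with the published mean and SD of
#' the chosen feature — the minimal generative model consistent with
#' reported summary statistics. Draws outside a feature's theoretical range
#' (e.g. correlation above 1) are clipped, and the clipped fraction is
#' attached as attribute `clip_fraction`.
#'
#' @param feature feature name (see [feature_names()]).
#' @param n_per_group subjects per group; `NULL` uses the group sizes in
#'   `params`.
#' @param seed RNG seed.
#' @param params parameter list from [group_feature_params()].
#' @return data.frame with `score` and `group` columns (groups `"ARDS"`,
#'   `"CPE"`), attribute `clip_fraction`.
#' @export
#' @examples
#' sim <- simulate_group_features("correlation", n_per_group = 100, seed = 1)
#' tapply(sim$score, sim$group, mean)
simulate_group_features <- function(feature, n_per_group = NULL, seed = 1,
                                    params = group_feature_params()) {
  if (!feature %in% names(params$features))
    stop("unknown feature: ", feature, call. = FALSE)
  fp <- params$features[[feature]]
  groups <- names(fp)
  ns <- if (is.null(n_per_group)) {
    vapply(groups, function(g) as.integer(params$groups[[g]]$n_subjects),
           integer(1))
  } else rep(as.integer(n_per_group), length(groups))
  set.seed(seed)
  bounds <- feature_bounds(feature)
  scores <- numeric(0); label <- character(0); clipped <- 0L
  for (gi in seq_along(groups)) {
    x <- stats::rnorm(ns[gi], fp[[groups[gi]]]$mean, fp[[groups[gi]]]$sd)
    clipped <- clipped + sum(x < bounds[1] | x > bounds[2])
    x <- pmin(bounds[2], pmax(bounds[1], x))
    scores <- c(scores, x)
    label <- c(label, rep(groups[gi], ns[gi]))
  }
  out <- data.frame(score = scores, group = label, stringsAsFactors = FALSE)
  attr(out, "clip_fraction") <- clipped / sum(ns)
  out
}
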