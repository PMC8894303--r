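#' Texture features of one frame within an ROI
#'
#' Runs the full per-frame chain: quantize the frame, rasterize the ROI,
#' compute one GLCM per (distance, angle) in the configuration, and reduce to
#' a single feature vector. With `averaging = "feature"` (default) features
#' are computed per matrix and averaged across all (d, angle) pairs; with
#' `"matrix"` the directional matrices are averaged per distance first,
#' features computed per distance, then averaged over distances. Undefined
#' correlations (constant ROI for some matrix) are excluded from the
#' correlation average only.
#'
#' @param frame a [grey_frame()].
#' @param roi an [roi_shape()], an [roi_mask()], or `NULL` for the full frame.
#' @param cfg a [glcm_config()].
#' @return A `texture_features` vector.
#' @export
#' @examples
#' f <- grey_frame(matrix(rep(c(0L, 255L), each = 8, times = 8), 16, 16))
#' analyze_frame(f, NULL, glcm_config(distances = 1))
analyze_frame <- function(frame, roi = NULL, cfg = glcm_config()) {
  stopifnot(inherits(cfg, "glcm_config"))
  q <- quantize(frame, cfg$n_levels)
  mask <- if (is.null(roi)) {
    full_mask(nrow(frame), ncol(frame))
  } else if (inherits(roi, "roi_mask")) {
    if (!all(dim(roi) == dim(frame)))
      stop("mask shape must equal frame shape", call. = FALSE)
    roi
  } else {
    rasterize(roi, nrow(frame), ncol(frame))
  }
  if (cfg$averaging == "feature") {
    feats <- lapply(cfg$distances, function(d)
      lapply(cfg$angles, function(a)
        compute_features(compute_glcm(q, mask, d, a))))
    feats <- unlist(feats, recursive = FALSE)
  } else {
    feats <- lapply(cfg$distances, function(d) {
      dir_mats <- lapply(cfg$angles, function(a) compute_glcm(q, mask, d, a))
      compute_features(average_glcms(dir_mats))
    })
  }
  mean_features(feats)
}

# Mean of feature vectors; NA correlations dropped from the correlation mean.
mean_features <- function(feats) {
  mat <- do.call(rbind, lapply(feats, unclass))
  out <- colMeans(mat)
  out["correlation"] <- if (all(is.na(mat[, "correlation"]))) NA_real_ else
    mean(mat[, "correlation"], na.rm = TRUE)
  structure(out, class = "texture_features")
}

#' Aggregate per-zone features to per-subject features
#'
#' Each subject's feature vector is the arithmetic mean of the zone feature
#' vectors (the mean of the findings of the 12 scanned areas is the unit of
#' statistical analysis). Subjects with fewer than 12 available zones are
#' averaged over the available ones, with `n_zones` recording how many.
#' Zones whose correlation is undefined are excluded from the correlation
#' mean only.
#'
#' @param records data.frame with columns `subject_id`, `zone_id` and one
#'   column per feature (as written by [write_feature_table()]).
#' @param group_map named character vector or data.frame
#'   (`subject_id`, `group`) mapping every subject to its group
#'   (e.g. `"ARDS"`, `"CPE"`, `"HCG"`).
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `n_zones`, then the mean features. Row order follows the first
#'   appearance of each subject; the result is invariant to record order.
#' @export
aggregate_zones <- function(records, group_map) {
  df <- as_feature_df(records)
  if (nrow(df) == 0) stop("no zone records to aggregate", call. = FALSE)
  if (is.data.frame(group_map))
    group_map <- stats::setNames(as.character(group_map$group),
                                 as.character(group_map$subject_id))
  subjects <- unique(df$subject_id)
  missing <- setdiff(subjects, names(group_map))
  if (length(missing) > 0)
    stop("subjects missing from group map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  feats <- setdiff(names(df), c("subject_id", "zone_id", "group"))
  rows <- lapply(subjects, function(s) {
    sub <- df[df$subject_id == s, feats, drop = FALSE]
    sub <- sub[order(df$zone_id[df$subject_id == s]), , drop = FALSE]
    mu <- vapply(feats, function(f) {
      x <- sub[[f]]
      if (f == "correlation") mean(x, na.rm = TRUE) else mean(x)
    }, numeric(1))
    cbind(data.frame(subject_id = s, group = unname(group_map[s]),
                     n_zones = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(as.list(mu)))
  })
  do.call(rbind, rows)
}

#' Extract features for every record of a run manifest
#'
#' The manifest is a JSON file with a `records` array; each record has
#' `path` (image file), optional `frame` (1-based index into a clip; a vector
#' of indices averages the per-frame features, default is the single first
#' frame), `subject_id`, `zone_id`, and an optional `roi` object
#' (`{"kind": ..., "vertices": [[row, col], ...]}`; absent means full frame).
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest JSON.
#' @param cfg a [glcm_config()].
#' @param out_csv optional path: write the feature table with
#'   [write_feature_table()] and a JSON sidecar `<out>.manifest.json`
#'   recording the configuration, file list and package version.
#' @return The per-zone feature data.frame, invisibly if `out_csv` is given.
#' @export
extract_features <- function(manifest_path, cfg = glcm_config(), out_csv = NULL) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  recs <- man$records
  if (is.null(recs) || length(recs) == 0)
    stop("manifest has no records", call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  rows <- lapply(recs, function(r) {
    path <- r$path
    if (!file.exists(path)) path <- file.path(base, r$path)
    idx <- if (is.null(r$frame)) 1L else as.integer(unlist(r$frame))
    frames <- read_frames(path, frame_index = idx)
    roi <- if (is.null(r$roi)) NULL else
      roi_shape(r$roi$kind, lapply(r$roi$vertices, unlist))
    fv <- mean_features(lapply(frames, analyze_frame, roi = roi, cfg = cfg))
    list(subject_id = r$subject_id, zone_id = r$zone_id, features = fv)
  })
  df <- as_feature_df(rows)
  if (!is.null(out_csv)) {
    write_feature_table(df, out_csv)
    sidecar <- list(
      config = unclass(cfg),
      files = vapply(recs, function(r) r$path, character(1)),
      package_version = as.character(utils::packageVersion("pleuratex")))
    jsonlite::write_json(sidecar, paste0(out_csv, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(df))
  }
  df
}
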