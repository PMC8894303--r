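#' Empirical ROC curve with Youden cut-off
#'
#' Builds the empirical ROC over all unique thresholds, computes the AUC by
#' the trapezoidal rule, and picks the cut-off maximizing Youden's
#' J = sensitivity + specificity - 1. The scoring direction is chosen so
#' that AUC >= 0.5 ("higher-positive" when larger scores indicate the
#' positive class, "lower-positive" otherwise). Ties on J are broken in
#' favour of the cut-off with higher sensitivity; cut-offs are reported as
#' midpoints between adjacent distinct scores (half a step beyond the
#' extremes at the ends).
#'
#' @param scores numeric vector, no missing values.
#' @param labels vector of class labels, two classes present.
#' @param positive the label counted as positive.
#' @param ci `"bootstrap"` (percentile, default), `"delong"`
#'   (DeLong-variance normal interval) or `"none"`.
#' @param n_boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap CI.
#' @return An object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `cutoff`, `sensitivity`, `specificity`, `direction`, plus the
#'   full curve (`fpr`, `tpr`, `thresholds`).
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c("a", "a", "b", "b"), positive = "b", ci = "none")
roc_curve <- function(scores, labels, positive, ci = c("bootstrap", "delong", "none"),
                      n_boot = 2000, conf = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  y <- labels == positive
  if (!any(y) || all(y))
    stop("both classes must be present", call. = FALSE)
  direction <- "higher-positive"
  if (auc_mwu(scores, y) < 0.5) {
    direction <- "lower-positive"
  }
  s <- if (direction == "higher-positive") scores else -scores
  curve <- roc_points(s, y)
  auc <- trapezoid_auc(curve$fpr, curve$tpr)
  jj <- curve$tpr - curve$fpr
  best <- which(jj == max(jj))
  best <- best[which.max(curve$tpr[best])]  # tie -> higher sensitivity
  cutoff <- curve$thresholds[best]
  if (direction == "lower-positive") cutoff <- -cutoff
  res <- list(auc = auc, ci_low = NA_real_, ci_high = NA_real_,
              cutoff = cutoff, sensitivity = curve$tpr[best],
              specificity = 1 - curve$fpr[best], direction = direction,
              fpr = curve$fpr, tpr = curve$tpr,
              thresholds = if (direction == "lower-positive")
                -curve$thresholds else curve$thresholds,
              n_pos = sum(y), n_neg = sum(!y))
  if (ci == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    ip <- which(y); ineg <- which(!y)
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(resample(ip), resample(ineg))
      auc_mwu(s[idx], y[idx])
    }, numeric(1))
    qs <- stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    res$ci_low <- qs[1]; res$ci_high <- qs[2]
  } else if (ci == "delong") {
    v <- delong_var(s, y)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    res$ci_low <- max(0, auc - z * sqrt(v))
    res$ci_high <- min(1, auc + z * sqrt(v))
  }
  structure(res, class = "roc_result")
}

# length-safe resample with replacement (sample() treats a scalar as 1:n)
resample <- function(idx) idx[sample.int(length(idx), length(idx), replace = TRUE)]

# AUC as the Mann-Whitney U statistic / (n_pos * n_neg), ties counted 1/2.
auc_mwu <- function(scores, y) {
  r <- rank(scores)
  n_pos <- as.numeric(sum(y)); n_neg <- as.numeric(sum(!y))
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Empirical ROC points over all unique thresholds (midpoints between
# adjacent distinct scores, plus half-step sentinels at both ends).
# Cumulative-count formulation: O(n log n).
roc_points <- function(s, y) {
  u <- sort(unique(s))
  m <- length(u)
  step <- if (m > 1) diff(range(u)) / (m - 1) else 1
  thr <- c(u[1] - step / 2,
           if (m > 1) (u[-1] + u[-m]) / 2 else numeric(0),
           u[m] + step / 2)
  bin <- match(s, u)
  pos_at <- tabulate(bin[y], m)
  neg_at <- tabulate(bin[!y], m)
  # at threshold thr[k] (k <= m): predicted positive iff s >= u[k]
  tp <- c(rev(cumsum(rev(pos_at))), 0)
  fp <- c(rev(cumsum(rev(neg_at))), 0)
  list(fpr = fp / sum(!y), tpr = tp / sum(y), thresholds = thr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- fpr[o]; yy <- tpr[o]
  sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
}

# DeLong variance of the empirical AUC (placement-value decomposition).
delong_var <- function(s, y) {
  sp <- s[y]; sn <- s[!y]
  m <- length(sp); n <- length(sn)
  v10 <- vapply(sp, function(x) (sum(x > sn) + 0.5 * sum(x == sn)) / n, numeric(1))
  v01 <- vapply(sn, function(x) (sum(sp > x) + 0.5 * sum(sp == x)) / m, numeric(1))
  stats::var(v10) / m + stats::var(v01) / n
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (CI %.3f-%.3f), cut-off %.4g (%s)\n",
              x$auc, x$ci_low, x$ci_high, x$cutoff, x$direction))
  cat(sprintf("  sensitivity %.3f, specificity %.3f (n+ = %d, n- = %d)\n",
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(x$fpr, x$tpr)
  graphics::plot(x$fpr[o], x$tpr[o], type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Bootstrap comparison of two paired AUCs
#'
#' Compares the AUCs of two features measured on the same subjects by
#' resampling subjects with replacement (stratified by class so both groups
#' survive every replicate), recomputing the AUC difference per replicate,
#' and reading a two-sided p-value off the normal approximation to the
#' bootstrap distribution of the difference.
#'
#' @param scores_a,scores_b paired numeric score vectors (same subjects).
#' @param labels class labels.
#' @param positive the positive label.
#' @param n_boot bootstrap replicates (default 2000; < 100 warns).
#' @param seed RNG seed for reproducibility.
#' @return List with `p_value`, `auc_a`, `auc_b`, `delta_observed`,
#'   `delta_boot_sd`, `n_boot`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels, positive,
                                  n_boot = 2000, seed = NULL) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must be paired", call. = FALSE)
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  y <- labels == positive
  oriented_auc <- function(s, yy) max(auc_mwu(s, yy), 1 - auc_mwu(s, yy))
  auc_a <- oriented_auc(scores_a, y)
  auc_b <- oriented_auc(scores_b, y)
  delta_obs <- auc_a - auc_b
  ip <- which(y); ineg <- which(!y)
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- c(resample(ip), resample(ineg))
    oriented_auc(scores_a[idx], y[idx]) - oriented_auc(scores_b[idx], y[idx])
  }, numeric(1))
  sd_d <- stats::sd(deltas)
  p <- if (sd_d == 0) {
    if (abs(delta_obs) < .Machine$double.eps) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta_obs) / sd_d)
  }
  list(p_value = min(p, 1), auc_a = auc_a, auc_b = auc_b,
       delta_observed = delta_obs, delta_boot_sd = sd_d, n_boot = n_boot)
}

#' Cross-validated classification error of a single-feature Youden rule
#'
#' Stratified k-fold cross-validation of the one-feature threshold
#' classifier: on each training fold the Youden cut-off and scoring
#' direction are fitted, then applied to the held-out subjects; the error is
#' the pooled misclassification fraction. If the minority class has fewer
#' members than `k`, the split degrades to leave-one-out with a warning.
#'
#' @param scores numeric feature values.
#' @param labels class labels.
#' @param positive the positive label.
#' @param k number of folds (default 4).
#' @param seed RNG seed for the fold assignment.
#' @return List with `error`, `k`, `n`, and the per-subject `predicted`
#'   logical vector (TRUE = called positive).
#' @export
cv_error <- function(scores, labels, positive, k = 4, seed = NULL) {
  y <- labels == positive
  n <- length(y)
  if (min(sum(y), sum(!y)) < k) {
    warning("minority class smaller than k; using leave-one-out")
    k <- n
    folds <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    folds <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      pool <- which(y == cls)
      idx <- pool[sample.int(length(pool))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  pred <- logical(n)
  for (f in unique(folds)) {
    test <- folds == f
    r <- roc_curve(scores[!test], labels[!test], positive, ci = "none")
    pred[test] <- if (r$direction == "higher-positive")
      scores[test] > r$cutoff else scores[test] < r$cutoff
  }
  list(error = mean(pred != y), k = k, n = n, predicted = pred)
}

#' Inter-rater agreement: two-way absolute-agreement ICC and Cronbach's alpha
#'
#' Single-measure intraclass correlation under the two-way random-effects
#' absolute-agreement model, ICC(2,1), from the standard mean-squares
#' decomposition of the subjects x raters table, with an F-based confidence
#' interval; Cronbach's alpha as the companion internal-consistency
#' coefficient.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   complete (no missing cells), >= 2 raters and >= 2 subjects.
#' @param conf confidence level for the ICC interval.
#' @return An object of class `agreement_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `cronbach_alpha`, `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)     # between-subjects
  msc <- ss_cols / (k - 1)     # between-raters
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= mse && abs(denom) < .Machine$double.eps) {
    warning("zero between-subject variance; ICC set to 0")
    icc <- 0
  } else {
    icc <- (msr - mse) / denom
  }
  # McGraw & Wong F-based interval for ICC(A,1)
  if (mse > 0 && icc < 1) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - (1 - conf) / 2, n - 1, v)
    fu <- stats::qf(1 - (1 - conf) / 2, v, n - 1)
    ci_low <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci_low <- max(-1, min(ci_low, icc))
    ci_high <- min(1, max(ci_high, icc))
  } else {
    ci_low <- icc; ci_high <- icc
  }
  var_sum <- stats::var(rowSums(ratings))
  alpha <- if (var_sum > 0) {
    k / (k - 1) * (1 - sum(apply(ratings, 2, stats::var)) / var_sum)
  } else 1
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 cronbach_alpha = alpha, n_subjects = n, n_raters = k),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> ICC(2,1) %.3f (CI %.3f-%.3f), Cronbach alpha %.3f (%d subjects x %d raters)\n",
              x$icc, x$ci_low, x$ci_high, x$cronbach_alpha,
              x$n_subjects, x$n_raters))
  invisible(x)
}
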