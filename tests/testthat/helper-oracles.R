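# Independent oracles used by the test suite. These deliberately use naive
# enumeration, not the package's vectorized code paths.

# Brute-force GLCM: explicit double loop over every pixel pair.
bf_glcm <- function(lv, ng, mask, d, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  cnt <- matrix(0, ng, ng)
  nr <- nrow(lv); nc <- ncol(lv)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, cc] && mask[r2, c2]) {
      i <- lv[r, cc] + 1L; j <- lv[r2, c2] + 1L
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
  }
  list(p = cnt / sum(cnt), n_pairs = sum(cnt))
}

# Brute-force feature evaluator: loops over all (i, j) and all k.
bf_features <- function(p) {
  ng <- nrow(p); lv <- 0:(ng - 1)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))
  con <- sh <- pr <- ent <- va <- co <- en <- ho <- 0
  for (i in lv) for (j in lv) {
    pij <- p[i + 1, j + 1]
    con <- con + (i - j)^2 * pij
    sh <- sh + (i + j - mux - muy)^3 * pij
    pr <- pr + (i + j - mux - muy)^4 * pij
    if (pij > 0) ent <- ent - pij * log2(pij)
    va <- va + (i - mux)^2 * pij
    co <- co + (i - mux) * (j - muy) * pij
    en <- en + pij^2
    ho <- ho + pij / (1 + (i - j)^2)
  }
  ps <- numeric(2 * ng - 1)
  for (i in lv) for (j in lv) ps[i + j + 1] <- ps[i + j + 1] + p[i + 1, j + 1]
  ks <- 0:(2 * ng - 2)
  ms <- sum(ks * ps)
  es <- 0
  for (k in seq_along(ps)) if (ps[k] > 0) es <- es - ps[k] * log2(ps[k])
  vs <- sum((ks - ms)^2 * ps)
  c(contrast = con, cluster_shade = sh, cluster_prominence = pr, entropy = ent,
    variance = va, mean = (mux + muy) / 2,
    correlation = if (sx > 0) co / (sx * sy) else NA_real_,
    energy = en, homogeneity = ho, mean_sum = ms, entropy_sum = es,
    variance_sum = vs)
}

# Random normalized symmetric matrix wrapped as a glcm object.
rand_glcm <- function(ng = 16) {
  m <- matrix(stats::rexp(ng * ng), ng)
  m <- m + t(m)
  m <- m / sum(m)
  structure(m, n_levels = as.integer(ng), d = 1L, angle = 0, n_pairs = 100,
            class = c("glcm", "matrix"))
}

# Independent even-odd point-in-polygon test for a single pixel center,
# casting the ray in the +row direction (the package casts along +col),
# with an explicit point-on-segment boundary check.
pip_oracle <- function(pr, pc, v) {
  n <- nrow(v)
  jj <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    r1 <- v[jj, 1]; c1 <- v[jj, 2]; r2 <- v[i, 1]; c2 <- v[i, 2]
    cross <- (c2 - c1) * (pr - r1) - (r2 - r1) * (pc - c1)
    if (abs(cross) < 1e-9 &&
        pr >= min(r1, r2) - 1e-9 && pr <= max(r1, r2) + 1e-9 &&
        pc >= min(c1, c2) - 1e-9 && pc <= max(c1, c2) + 1e-9)
      return(TRUE)
    if ((c1 > pc) != (c2 > pc)) {
      r_at <- (r2 - r1) * (pc - c1) / (c2 - c1) + r1
      if (pr < r_at) inside <- !inside
    }
    jj <- i
  }
  inside
}

# Random test frame + random rectangular-blob mask with >= 2 inside pixels.
rand_frame_and_mask <- function(max_side = 32) {
  h <- sample(5:max_side, 1); w <- sample(5:max_side, 1)
  f <- grey_frame(matrix(sample(0:255, h * w, TRUE), h, w))
  mask <- matrix(runif(h * w) < 0.7, h, w)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  mask <- structure(mask, n_inside = sum(mask), class = c("roi_mask", "matrix"))
  list(frame = f, mask = mask)
}

# ANOVA-table ICC(2,1) oracle via stats::aov.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::aov(y ~ subj + rater, df))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  system.file("cli", "pleuratex.R", package = "pleuratex", mustWork = TRUE)
}
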