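# grey value whose Ng=16 level equals the requested level
real_grey <- function(lv) as.integer(lv * 16L)

test_that("quantization follows floor(grey * Ng / 256) for every grey value", {
  f <- grey_frame(matrix(0:255, 16, 16))
  q <- quantize(f, 16)
  expect_identical(as.vector(unclass(q)), as.integer(floor((0:255) * 16 / 256)))
  expect_equal(unclass(q)[1, 1], 0L)        # grey 0
  expect_equal(unclass(q)[16, 16], 15L)     # grey 255
  expect_equal(unclass(quantize(f, 16))[17], 1L)  # grey 16 -> level 1
  expect_equal(unclass(quantize(f, 16))[16], 0L)  # grey 15 -> level 0
  # monotone non-decreasing for every Ng
  for (ng in c(2, 3, 16, 256))
    expect_true(all(diff(as.vector(unclass(quantize(f, ng)))) >= 0))
  expect_error(quantize(f, 1), "n_levels")
})

test_that("constant and two-level frames give the hand-enumerated matrices", {
  q <- quantize(grey_frame(matrix(real_grey(5), 2, 2)), 16)
  g <- compute_glcm(q, d = 1, angle = 0)
  expect_equal(g[6, 6], 1)
  expect_equal(attr(g, "n_pairs"), 4)
  expect_equal(sum(g), 1)

  # columns 0 and 1: two horizontal pairs, symmetrized
  q2 <- quantize(grey_frame(matrix(real_grey(c(0, 0, 1, 1)), 2, 2)), 16)
  g2 <- compute_glcm(q2, d = 1, angle = 0)
  expect_equal(g2[1, 2], 0.5)
  expect_equal(g2[2, 1], 0.5)
  expect_equal(attr(g2, "n_pairs"), 4)
})

test_that("masked GLCM equals the brute-force pair enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    fm <- rand_frame_and_mask(max_side = 24)
    q <- quantize(fm$frame, 16)
    d <- sample(1:4, 1); ang <- sample(c(0, 45, 90, 135), 1)
    ref <- bf_glcm(unclass(q), 16, unclass(fm$mask), d, ang)
    if (ref$n_pairs == 0) {
      expect_error(compute_glcm(q, fm$mask, d, ang), "no valid pixel pairs")
      next
    }
    g <- compute_glcm(q, fm$mask, d, ang)
    expect_lt(max(abs(unclass(g) - ref$p)), 1e-12)
    expect_equal(attr(g, "n_pairs"), ref$n_pairs)
  }
})

test_that("GLCMs are symmetric, normalized, and direction-sign invariant", {
  set.seed(32)
  fm <- rand_frame_and_mask()
  q <- quantize(fm$frame, 16)
  for (ang in c(0, 45, 90, 135)) for (d in 1:3) {
    g <- compute_glcm(q, fm$mask, d, ang)
    expect_equal(max(abs(unclass(g) - t(unclass(g)))), 0)
    expect_lt(abs(sum(g) - 1), 1e-9)
    expect_equal(rowSums(unclass(g)), colSums(unclass(g)))
  }
  # theta and theta + 180 are equivalent: offsets (0, d) and (0, -d) count
  # the same symmetrized pairs; check via the brute-force oracle
  ref_fwd <- bf_glcm(unclass(q), 16, unclass(fm$mask), 2, 0)
  lvr <- unclass(q)[, ncol(q):1]
  mskr <- unclass(fm$mask)[, ncol(q):1]
  ref_rev <- bf_glcm(lvr, 16, mskr, 2, 0)  # mirrored frame = reversed offset
  expect_equal(ref_fwd$p, ref_rev$p)
})

test_that("a full-true mask reproduces the unmasked computation", {
  set.seed(33)
  f <- grey_frame(matrix(sample(0:255, 30 * 20, TRUE), 30, 20))
  q <- quantize(f, 16)
  for (ang in c(0, 45, 90, 135)) {
    g1 <- compute_glcm(q, NULL, 2, ang)
    g2 <- compute_glcm(q, full_mask(30, 20), 2, ang)
    expect_identical(unclass(g1), unclass(g2))
  }
})

test_that("averaging GLCMs is the entrywise mean and keeps invariants", {
  set.seed(34)
  f <- grey_frame(matrix(sample(0:255, 400, TRUE), 20, 20))
  q <- quantize(f, 16)
  mats <- lapply(c(0, 45, 90, 135), function(a) compute_glcm(q, NULL, 1, a))

  av_self <- average_glcms(list(mats[[1]], mats[[1]]))
  expect_equal(unclass(av_self), unclass(mats[[1]]), ignore_attr = TRUE)

  m1 <- rand_glcm(2); m2 <- rand_glcm(2)
  m1[] <- matrix(c(0, 0.5, 0.5, 0), 2)
  m2[] <- matrix(c(0.5, 0, 0, 0.5), 2)
  av <- average_glcms(list(m1, m2))
  expect_equal(as.vector(unclass(av)), rep(0.25, 4))

  av4 <- average_glcms(mats)
  expect_lt(abs(sum(av4) - 1), 1e-9)
  expect_equal(unclass(av4), t(unclass(av4)))
  expect_identical(attr(av4, "angle"), "averaged")
  expect_error(average_glcms(list()), "non-empty")
})

test_that("empty ROIs are rejected", {
  q <- quantize(grey_frame(matrix(0L, 4, 4)), 16)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE; mask[4, 4] <- TRUE  # no pair at d=1
  mask <- structure(mask, n_inside = 2L, class = c("roi_mask", "matrix"))
  expect_error(compute_glcm(q, mask, 1, 0), "no valid pixel pairs")
})
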