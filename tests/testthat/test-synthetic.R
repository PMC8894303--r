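test_that("phantom generation is pure in (spec, seed)", {
  s <- phantom_spec("healthy", seed = 9)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(unclass(a), unclass(b))
  c <- generate_phantom(phantom_spec("healthy", seed = 10))
  expect_false(identical(unclass(a), unclass(c)))
  # generation must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_phantom(s)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("phantom classes carry the expected texture signatures", {
  cfg <- glcm_config(distances = 1)
  fv_h <- analyze_frame(generate_phantom(phantom_spec("healthy", seed = 1)), NULL, cfg)
  fv_c <- analyze_frame(generate_phantom(phantom_spec("cpe", seed = 1)), NULL, cfg)
  fv_a <- analyze_frame(generate_phantom(phantom_spec("ards", seed = 1)), NULL, cfg)
  expect_gt(fv_h[["cluster_shade"]], 0)   # bright blobs on darker background
  expect_lt(fv_c[["cluster_shade"]], 0)   # dark blobs on lighter background
  expect_gt(fv_a[["correlation"]], fv_c[["correlation"]])  # uniform patches
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec("healthy", blob_radius = 60), "blob_radius")
  expect_error(phantom_spec("cpe", blob_density = 0), "blob_density")
  expect_error(phantom_spec("ards", background_level = 300), "grey levels")
})

test_that("the packaged group parameters load and validate", {
  prm <- group_feature_params()
  expect_setequal(names(prm$features),
                  setdiff(feature_names(), "cluster_prominence"))
  expect_equal(prm$groups$ARDS$n, 8)
  expect_equal(prm$groups$CPE$n, 16)
  for (f in names(prm$features))
    for (g in c("ARDS", "CPE"))
      expect_gt(prm$features[[f]][[g]]$sd, 0)
})

test_that("feature simulation is reproducible and respects group parameters", {
  a <- simulate_group_features("correlation", n_per_group = 50, seed = 4)
  b <- simulate_group_features("correlation", n_per_group = 50, seed = 4)
  expect_identical(a, b)
  expect_equal(table(a$group)[["ARDS"]], 50)

  # default group sizes come from the parameter file
  d <- simulate_group_features("contrast", seed = 1)
  expect_equal(sum(d$group == "ARDS"), 8)
  expect_equal(sum(d$group == "CPE"), 16)
  expect_error(simulate_group_features("no_such_feature"), "unknown feature")
})

test_that("sample moments converge to the generative parameters", {
  sim <- simulate_group_features("correlation", n_per_group = 1e5, seed = 2)
  prm <- group_feature_params()$features$correlation
  for (g in c("ARDS", "CPE")) {
    x <- sim$score[sim$group == g]
    se <- prm[[g]]$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - prm[[g]]$mean), 3 * se + 1e-4)  # + clip allowance
  }
  expect_lt(attr(sim, "clip_fraction"), 0.001)
})

test_that("a near-degenerate SD collapses all draws onto the mean", {
  prm <- list(groups = list(A = list(n = 5), B = list(n = 5)),
              features = list(f = list(A = list(mean = 2, sd = 1e-12),
                                       B = list(mean = 7, sd = 1e-12))))
  sim <- simulate_group_features("f", n_per_group = 20, seed = 3, params = prm)
  expect_equal(sim$score[sim$group == "A"], rep(2, 20), tolerance = 1e-9)
  expect_equal(sim$score[sim$group == "B"], rep(7, 20), tolerance = 1e-9)
})

test_that("empirical AUC of simulated features approaches the binormal closed form", {
  prm <- group_feature_params()$features$homogeneity
  sim <- simulate_group_features("homogeneity", n_per_group = 2e4, seed = 5)
  a <- roc_curve(sim$score, sim$group, "ARDS", ci = "none")$auc
  binormal <- stats::pnorm(abs(prm$ARDS$mean - prm$CPE$mean) /
                             sqrt(prm$ARDS$sd^2 + prm$CPE$sd^2))
  expect_lt(abs(a - binormal), 0.01)
})
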