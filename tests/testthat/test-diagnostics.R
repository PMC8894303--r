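test_that("perfectly separated scores give AUC 1 at the midpoint cut-off", {
  r <- roc_curve(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p", ci = "none")
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$direction, "higher-positive")
  # reversed polarity is detected
  r2 <- roc_curve(c(4, 3, 2, 1), c("p", "p", "n", "n"), "n", ci = "none")
  expect_equal(r2$auc, 1)
  expect_equal(r2$direction, "lower-positive")
  expect_error(roc_curve(1:4, rep("p", 4), "p"), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney U identity, ties counted half", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    s <- sample(1:8, n, TRUE)  # heavy ties
    y <- sample(c("a", "b"), n, TRUE)
    if (length(unique(y)) < 2) next
    r <- roc_curve(s, y, "b", ci = "none")
    u <- unname(stats::wilcox.test(s[y == "b"], s[y == "a"], exact = FALSE)$statistic)
    auc_u <- u / (sum(y == "b") * sum(y == "a"))
    expect_equal(r$auc, max(auc_u, 1 - auc_u), tolerance = 1e-12)
  }
})

test_that("bootstrap CI works with a single subject per class", {
  r <- roc_curve(c(1.2, 3.4), c("ARDS", "CPE"), "ARDS", seed = 1)
  expect_equal(r$auc, 1)
  expect_false(anyNA(c(r$ci_low, r$ci_high)))
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(62)
  s <- rnorm(40); y <- rep(c("a", "b"), 20)
  a0 <- roc_curve(s, y, "b", ci = "none")$auc
  expect_equal(roc_curve(exp(s), y, "b", ci = "none")$auc, a0)
  expect_equal(roc_curve(10 * s - 3, y, "b", ci = "none")$auc, a0)
})

test_that("ROC agrees with an independent implementation", {
  set.seed(63)
  s <- rnorm(80); y <- ifelse(runif(80) < stats::plogis(1.5 * s), "p", "n")
  mine <- roc_curve(s, y, "p", ci = "none")$auc
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, levels = c("n", "p"), direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("AUC approaches 0.5 when labels are independent of scores", {
  set.seed(64)
  r <- roc_curve(rnorm(4000), sample(rep(c("a", "b"), 2000)), "b", ci = "none")
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("bootstrap AUC comparison: identity, power and determinism", {
  set.seed(65)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  sep <- c(rnorm(n / 2), rnorm(n / 2) + 10)  # perfectly separating
  noise <- rnorm(n)                          # uninformative
  same <- compare_auc_bootstrap(sep, sep, y, "b", seed = 1)
  expect_equal(same$p_value, 1)
  diff <- compare_auc_bootstrap(sep, noise, y, "b", seed = 2)
  expect_lt(diff$p_value, 0.01)
  diff2 <- compare_auc_bootstrap(sep, noise, y, "b", seed = 2)
  expect_identical(diff$p_value, diff2$p_value)
  expect_warning(compare_auc_bootstrap(sep, noise, y, "b", n_boot = 50, seed = 1),
                 "fewer than 100")
})

test_that("fourfold CV error is 0 on separable data and ~0.5 on permuted labels", {
  sep <- cv_error(c(1:12, 101:112), rep(c("a", "b"), each = 12), "b", seed = 1)
  expect_equal(sep$error, 0)
  set.seed(66)
  null <- cv_error(rnorm(2000), sample(rep(c("a", "b"), 1000)), "b", seed = 2)
  expect_lt(abs(null$error - 0.5), 0.05)
})

test_that("CV degrades to leave-one-out when the minority class is tiny", {
  scores <- c(1, 2, 3, 100, 101, 4, 5, 6)
  labels <- c("a", "a", "a", "b", "b", "a", "a", "a")
  expect_warning(r <- cv_error(scores, labels, "b", k = 4, seed = 1),
                 "leave-one-out")
  expect_equal(r$k, 8)
  expect_equal(r$error, 0)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle to 1e-10", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  got <- icc_agreement(m)
  expect_equal(got$icc, icc_oracle(m), tolerance = 1e-10)
  set.seed(67)
  for (rep in 1:10) {
    mm <- matrix(rnorm(3 * sample(4:12, 1)), ncol = 3)
    expect_equal(icc_agreement(mm)$icc, icc_oracle(mm), tolerance = 1e-10)
  }
})

test_that("duplicated raters give ICC 1 and alpha 1; pure noise gives ICC near 0", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  dup <- icc_agreement(cbind(x, x))
  expect_equal(dup$icc, 1)
  expect_equal(dup$cronbach_alpha, 1)
  set.seed(68)
  r1 <- rnorm(300)
  noisy <- icc_agreement(cbind(r1, rnorm(300, sd = 25)))
  expect_lt(abs(noisy$icc), 0.15)
  expect_warning(icc_agreement(matrix(5, 4, 2)), "zero between-subject")
})
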