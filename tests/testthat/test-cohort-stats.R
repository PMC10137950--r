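test_that("group comparison matches the textbook pooled t statistic", {
  d <- data.frame(v = c(41.2, 44.0, 39.5, 38.1, 36.2, 37.9),
                  sex = rep(c("men", "women"), each = 3))
  out <- group_compare(d, "v", "sex")
  x1 <- d$v[1:3]; x2 <- d$v[4:6]
  sp2 <- ((3 - 1) * var(x1) + (3 - 1) * var(x2)) / 4
  t_hand <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), 4)
  expect_equal(out$t, t_hand, tolerance = 1e-9)
  expect_equal(out$p_value, p_hand, tolerance = 1e-9)
  expect_equal(out$df, 4)

  # identical groups: t = 0, p = 1
  d2 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  out2 <- group_compare(d2, "v", "g")
  expect_equal(out2$t, 0)
  expect_equal(out2$p_value, 1)

  expect_error(group_compare(data.frame(v = 1:5, g = "a"), "v", "g"),
               "two groups")
})

test_that("the sex comparison is well powered at the reference effect size", {
  set.seed(501)
  rej <- vapply(1:1000, function(k) {
    x1 <- rnorm(28, 42.1, 4.8)
    x2 <- rnorm(38, 38.4, 3.6)
    stats::t.test(x1, x2, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.85)
})

test_that("t-test p-values are uniform under the null", {
  set.seed(502)
  ps <- vapply(1:1000, function(k) {
    stats::t.test(rnorm(20), rnorm(20), var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("correlation matches the direct product-moment formula", {
  d <- data.frame(x = c(1.2, 3.4, 2.2, 5.6, 4.4, 0.3),
                  y = c(2.0, 3.9, 2.4, 6.3, 4.1, 1.1))
  out <- correlate(d, "x", "y")
  r_hand <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
    sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)

  # exact linear relation
  d2 <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(correlate(d2, "x", "y")$r, 1, tolerance = 1e-12)
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "zero variance")
})

test_that("correlation is symmetric and affine-equivariant", {
  set.seed(33)
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  r1 <- correlate(d, "x", "y")$r
  expect_equal(correlate(d, "y", "x")$r, r1, tolerance = 1e-12)
  d$x2 <- 3 * d$x + 7
  expect_equal(correlate(d, "x2", "y")$r, r1, tolerance = 1e-12)
  d$x3 <- -2 * d$x
  expect_equal(correlate(d, "x3", "y")$r, -r1, tolerance = 1e-12)
})

test_that("independent variables rarely show spurious correlation at n = 66", {
  set.seed(503)
  small <- vapply(1:1000, function(k) {
    abs(cor(rnorm(66), rnorm(66))) < 0.25
  }, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("ICC(2,1) matches the ANOVA mean-square route and its oracle", {
  # duplicated ratings: perfect agreement
  x <- c(3.1, 4.5, 2.2, 5.0, 3.8, 4.1)
  expect_equal(icc(cbind(x, x))$icc, 1, tolerance = 1e-12)

  # hand fixture cross-checked against aov() mean squares
  m <- rbind(c(9, 2), c(8, 1), c(7, 3), c(6, 5), c(5, 4))
  out <- icc(m)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:5, 2)),
                     rater = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_aov <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 5)
  expect_equal(out$icc, icc_aov, tolerance = 1e-9)

  # variance components 9:1 give ICC about 0.9
  set.seed(504)
  vals <- vapply(1:200, function(k) {
    truth <- rnorm(30, 0, 3)
    icc(cbind(truth + rnorm(30), truth + rnorm(30)))$icc
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.9), 0.05)

  expect_error(icc(matrix(1, 6, 2)), "constant")
  expect_error(icc(matrix(rnorm(6), 3, 2)), ">= 5 subjects")
})

test_that("the cohort report carries tidy, glance and plot methods", {
  co <- generate_cohort(n = 12, seed = 29)
  me <- measure_cohort(co)
  st <- cohort_stats(me)
  td <- tidy(st)
  expect_true(all(c("type", "term", "estimate", "p_value") %in% names(td)))
  expect_true(any(td$type == "correlation"))
  gl <- glance(st)
  expect_equal(gl$n, 12)
  expect_true(is.finite(gl$r_fo_cup))
  expect_s3_class(autoplot(st), "ggplot")
  expect_s3_class(plot_offset_distribution(me), "ggplot")
  expect_s3_class(plot_offset_correlation(me), "ggplot")
})
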