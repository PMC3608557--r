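test_that("percent volume is exact voxel arithmetic", {
  expect_equal(percent_volume(binary_volume(array(TRUE, c(4, 4, 4)), 1)), 100)
  expect_equal(percent_volume(binary_volume(array(FALSE, c(4, 4, 4)), 1)), 0)
  v <- array(FALSE, c(30, 30, 30)); v[seq_len(27)] <- TRUE
  expect_equal(percent_volume(binary_volume(v, 1)), 0.1)

  # a rasterized tube occupies close to pi r^2 L
  cyl <- solid_cylinder_z(c(21, 21, 30), c(11, 11), 4)
  vp <- percent_volume(binary_volume(cyl, 1))
  expect_equal(vp, 100 * digital_disc_area(4) * 30 / (21 * 21 * 30))
  expect_lt(abs(vp - 100 * pi * 16 * 30 / (21 * 21 * 30)) / vp, 0.05)
})

test_that("median and IQR use the linear-interpolation percentile convention", {
  s <- summarize_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unname(s), c(3, 2, 4))
  expect_equal(unname(summarize_iqr(7)), c(7, 7, 7))
  set.seed(71)
  x <- rnorm(37)
  s2 <- summarize_iqr(x)
  expect_equal(s2[["q25"]], unname(quantile(x, 0.25)))
  expect_equal(s2[["q75"]], unname(quantile(x, 0.75)))
  expect_error(summarize_iqr(numeric(0)), "no values")
})

test_that("Welch's t-test matches the closed-form statistic", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.2)
  r <- welch_t(a, b)
  # independent closed-form computation
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                          (var(b) / length(b))^2 / (length(b) - 1))
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(r$statistic, t_manual, tolerance = 1e-10)
  expect_equal(r$df, df_manual, tolerance = 1e-10)
  expect_equal(r$p, p_manual, tolerance = 1e-10)

  # identical samples (shuffled): t = 0, p = 1
  x <- c(1.2, 3.4, 2.2, 5.1)
  r0 <- welch_t(x, sample(x))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # widely separated samples
  expect_lt(welch_t(rnorm(8, 0, 0.1), rnorm(8, 50, 0.1))$p, 0.001)
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("rank-sum test is exact for small untied samples", {
  # fully separated n = 4 vs 4: the most extreme rank assignment,
  # exact two-sided p = 2/70
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  r <- wilcoxon_rank(a, b)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 70, tolerance = 1e-12)
  expect_equal(r$p, oracle_ranksum_p(a, b), tolerance = 1e-12)

  # symmetric case
  expect_equal(wilcoxon_rank(c(1, 3, 5, 7), c(2, 4, 6, 8))$p,
               oracle_ranksum_p(c(1, 3, 5, 7), c(2, 4, 6, 8)), tolerance = 1e-12)

  set.seed(81)
  x <- rnorm(6); y <- rnorm(7, 0.5)
  expect_equal(wilcoxon_rank(x, y)$p, oracle_ranksum_p(x, y), tolerance = 1e-12)

  # ties or large samples switch to the normal approximation
  rt <- wilcoxon_rank(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_equal(rt$method, "normal_approx")
  expect_equal(wilcoxon_rank(rnorm(15), rnorm(15))$method, "normal_approx")
  expect_error(wilcoxon_rank(c(1, 1), c(1, 1)), "identical")

  # invariant under strictly monotone transforms
  expect_equal(wilcoxon_rank(x, y)$p, wilcoxon_rank(exp(x), exp(y))$p)
})

test_that("quadratic fit recovers coefficients and matches the normal equations", {
  v <- seq(0, 10, length.out = 21)
  y_exact <- 0.3 * v^2 - 2 * v + 5
  f <- quadratic_fit(v, y_exact)
  expect_equal(f$a, 0.3, tolerance = 1e-8)
  expect_equal(f$b, -2, tolerance = 1e-8)
  expect_equal(f$c, 5, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # 3 non-collinear points: exact interpolation, R^2 = 1
  f3 <- quadratic_fit(c(0, 1, 2), c(1, 0, 3))
  expect_equal(f3$r_squared, 1, tolerance = 1e-12)

  # noisy parabola vs closed-form normal equations
  set.seed(91)
  y <- y_exact + rnorm(21, 0, 0.8)
  f2 <- quadratic_fit(v, y)
  X <- cbind(1, v, v^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  expect_equal(c(f2$c, f2$b, f2$a), as.vector(beta), tolerance = 1e-8)
  expect_equal(f2$r_squared, 1 - rss / sum((y - mean(y))^2), tolerance = 1e-10)

  # R^2 invariant to linear rescaling of the abscissa
  f_resc <- quadratic_fit(3 * v + 7, y)
  expect_equal(f_resc$r_squared, f2$r_squared, tolerance = 1e-10)

  expect_error(quadratic_fit(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(quadratic_fit(c(1, 2), c(1, 2)), "3 points")
})

test_that("significance stars use strict thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.049, 0.05, 0.2)),
               c("***", "**", "*", "ns", "ns"))
  expect_equal(significance_stars(c(0.001, 0.01)), c("**", "*"))
})

test_that("the significance table flags identical cohorts ns and needs two arms", {
  set.seed(101)
  mk_metrics <- function(treatment, shift = 0) {
    do.call(rbind, lapply(1:6, function(s) {
      data.frame(sample = sprintf("%s_%d", treatment, s), treatment = treatment,
                 class = 1:6,
                 v_pct = abs(rnorm(6, 2 + shift, 0.3)),
                 nhv = rnorm(6, 10, 1))
    }))
  }
  a <- mk_metrics("ctrl")
  b <- a; b$treatment <- "drug"; b$sample <- sub("ctrl", "drug", a$sample)
  same <- build_significance_table(rbind(a, b))
  expect_true(all(same$tests$stars_v_pct == "ns"))
  expect_true(all(same$tests$p_v_pct == 1))

  expect_error(build_significance_table(a), "2 treatments")
  expect_error(build_significance_table(a[, -4]), "columns")

  # a planted 3x reduction is detected in v_pct
  set.seed(102)
  ctrl <- mk_metrics("ctrl", shift = 4)
  trt <- mk_metrics("rx", shift = -1.5)
  tab <- build_significance_table(rbind(ctrl, trt))
  expect_true(all(tab$tests$p_v_pct < 0.01))
})
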