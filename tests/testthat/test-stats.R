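test_that("noiseless lines are their own major axis", {
  x <- c(1, 2, 3, 5, 8)
  f <- ma_regression(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)
  f2 <- ma_regression(x, 2 * x + 1)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
})

test_that("the MA slope equals the perpendicular least-squares minimizer", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    b <- runif(1, -2, 2)
    x <- rnorm(n, sd = runif(1, 0.5, 2))
    y <- b * x + rnorm(n, sd = runif(1, 0.1, 1))
    fit <- ma_regression(x, y)
    expect_equal(fit$slope, oracle_ma_slope(x, y), tolerance = 1e-6)
  }
})

test_that("swapping the axes maps the slope to its reciprocal", {
  set.seed(22)
  x <- rnorm(100)
  y <- 0.6 * x + rnorm(100, sd = 0.4)
  f <- ma_regression(x, y)
  g <- ma_regression(y, x)
  expect_equal(g$slope, 1 / f$slope, tolerance = 1e-10)
})

test_that("MA exceeds OLS in magnitude whenever the fit is noisy", {
  set.seed(23)
  for (i in 1:10) {
    x <- as.numeric(scale(rnorm(150)))
    y <- as.numeric(scale(0.5 * x + rnorm(150, sd = 0.8)))
    fit <- ma_regression(x, y)
    ols <- unname(stats::coef(stats::lm(y ~ x))[2])
    expect_false(isTRUE(all.equal(fit$slope, ols)))
    expect_gte(abs(fit$slope) + 1e-12, abs(ols))
  }
})

test_that("MA confidence interval attains near-nominal coverage", {
  set.seed(24)
  hits <- 0
  for (i in 1:500) {
    p <- sample_aoo_pairs(100)
    f <- ma_regression(p$log10_nat, p$log10_thr)
    hits <- hits + (f$slope_ci_low <= 0.35 && 0.35 <= f$slope_ci_high)
  }
  expect_gte(hits / 500, 0.93)
  expect_lte(hits / 500, 0.97)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(ma_regression(1:2, 1:2), class = "natparadox_input_error")
  expect_error(ma_regression(1:3, c(1, 2)), class = "natparadox_input_error")
  expect_error(ma_regression(c(1, 2, 3), c(1, NA, 3)),
               class = "natparadox_input_error")
  # circular scatter: no direction minimizes perpendicular distance
  xy <- c(1, -1, 0, 0)
  expect_error(ma_regression(xy, c(0, 0, 1, -1)),
               class = "natparadox_degenerate_fit")
})

test_that("bootstrap CI broadly agrees with the analytic one", {
  set.seed(25)
  p <- sample_aoo_pairs(300)
  a <- ma_regression(p$log10_nat, p$log10_thr)
  b <- ma_regression(p$log10_nat, p$log10_thr, ci_method = "bootstrap",
                     n_boot = 500)
  expect_equal(a$slope, b$slope)
  expect_lt(abs(a$slope_ci_low - b$slope_ci_low), 0.1)
  expect_lt(abs(a$slope_ci_high - b$slope_ci_high), 0.1)
})

test_that("paired Wilcoxon matches exhaustive sign-assignment enumeration", {
  set.seed(26)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    b <- runif(n, 10, 100)
    a <- b + rnorm(n, sd = 20)
    res <- paired_wilcoxon(a, b)
    expect_equal(res$p_value, enum_wilcox_p(a - b), tolerance = 1e-12)
    expect_equal(res$method, "exact")
  }
})

test_that("a constant location shift is detected with its medians", {
  set.seed(27)
  b <- runif(30, 50, 150)
  a <- b + 10
  res <- paired_wilcoxon(a, b)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$median_a - res$median_b, 10)
  expect_equal(res$n_pairs, 30)
})

test_that("all-zero differences are an error unless pratt is requested", {
  a <- c(1, 2, 3)
  expect_error(paired_wilcoxon(a, a), class = "natparadox_input_error")
  expect_equal(paired_wilcoxon(a, a, zero_policy = "pratt")$p_value, 1)
})

test_that("compensation classes and percentages follow the differences", {
  parts <- tibble::tibble(
    species = sprintf("S sp%04d", 1:1716),
    aoo_naturalized = c(rep(100, 693), rep(900, 1023)),
    aoo_native_threatened = 500)
  out <- classify_compensation(parts)
  expect_equal(out$pct_partial_reported, 40.4)
  expect_equal(out$pct_net_reported, 59.6)
  expect_equal(out$pct_partial + out$pct_net, 100)
  expect_equal(out$n_tie, 0)
  # the reported medians order as a net increase
  one <- classify_compensation(tibble::tibble(
    species = "x", aoo_naturalized = 60593, aoo_native_threatened = 37066))
  expect_equal(one$results$klass, "net_increase")
})

test_that("ties and zero-AOO species are set aside, not misclassified", {
  parts <- tibble::tibble(
    species = c("a", "b", "c", "d"),
    aoo_naturalized = c(1000, 10, 0, 50),
    aoo_native_threatened = c(1000, 20, 30, 0))
  out <- classify_compensation(parts)
  expect_equal(out$n_tie, 1)
  expect_equal(out$n_excluded_zero_aoo, 2)
  expect_equal(out$pct_partial, 100)
})

test_that("Bland-Altman limits match direct recomputation", {
  set.seed(28)
  a <- rnorm(50, 5)
  b <- rnorm(50, 4.5)
  out <- bland_altman(a, b)
  expect_equal(out$mean_difference, mean(a - b))
  expect_equal(out$limits,
               mean(a - b) + c(-1.96, 1.96) * sd(a - b))
  cst <- bland_altman(b + 1, b)
  expect_equal(cst$mean_difference, 1)
  expect_equal(cst$limits, c(1, 1))
  expect_error(bland_altman(1, 2), class = "natparadox_input_error")
})

test_that("the percent-threatened histogram bins at width 5", {
  parts <- tibble::tibble(pct_native_threatened = c(0, 10, 20, NA))
  out <- pct_threatened_histogram(parts)
  expect_equal(out$mean, 10)
  expect_equal(out$median, 10)
  expect_equal(out$n_excluded, 1)
  expect_equal(out$bins$count[out$bins$bin_low %in% c(0, 10, 20)],
               c(1L, 1L, 1L))
  expect_equal(sum(out$bins$count), 3)
  top <- pct_threatened_histogram(
    tibble::tibble(pct_native_threatened = rep(100, 5)))
  expect_equal(top$mean, 100)
  expect_equal(top$bins$count[top$bins$bin_low == 95], 5L)
})
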