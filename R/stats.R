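#' Major axis (model II) regression
#'
#' Fits the major axis of the bivariate sample: the line through the
#' centroid along the leading eigenvector of the sample covariance matrix,
#' which minimizes the sum of squared perpendicular distances. Appropriate
#' when both variables carry error, as with two area-of-occupancy estimates.
#'
#' The slope is
#' `(s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`
#' and the intercept `ybar - slope * xbar`. The confidence interval uses the
#' classical F-based analytic form for the major-axis slope angle: the
#' angle `phi` between the sample axis and the true axis satisfies
#' `(n - 2) (l1/l2 + l2/l1 - 2) sin^2(2 phi) / 4 ~ F(1, n - 2)` with
#' `l1 >= l2` the covariance eigenvalues, so with
#' `H = F(1 - alpha; 1, n - 2) / ((l1/l2 + l2/l1 - 2) (n - 2))` the limits
#' are `tan(atan(slope) +- asin(2 sqrt(H)) / 2)`; `4 H >= 1` means the
#' axis orientation is unresolved and the interval is unbounded. A
#' percentile bootstrap alternative (2000 resamples) is available via
#' `ci_method = "bootstrap"`.
#'
#' @param x,y numeric vectors (here: log10 AOOs), equal length, finite.
#' @param ci_level confidence level (default 0.95).
#' @param ci_method `"analytic"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @return object of class `ma_fit`: list(`slope`, `intercept`,
#'   `slope_ci_low`, `slope_ci_high`, `n`, `r`, `ci_level`, `ci_method`).
#' @export
#' @examples
#' fit <- ma_regression(1:10, 2 * (1:10) + 1)
#' fit$slope # 2
ma_regression <- function(x, y, ci_level = 0.95, ci_method = c("analytic", "bootstrap"),
                          n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "natparadox_input_error")
  }
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep)) {
    abort("x and y must be finite (exclude zero-AOO species upstream)",
          class = "natparadox_input_error")
  }
  n <- length(x)
  if (n < 3) abort("major axis regression needs n >= 3",
                   class = "natparadox_input_error")

  slope_point <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxy == 0) {
      if (syy > sxx) return(Inf)
      if (syy < sxx) return(0)
      abort("degenerate fit: circular scatter has no major axis",
            class = "natparadox_degenerate_fit")
    }
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }

  b <- slope_point(x, y)
  a <- mean(y) - b * mean(x)
  r <- cor(x, y)

  if (ci_method == "bootstrap") {
    bs <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(n, n, replace = TRUE)
      tryCatch(slope_point(x[j], y[j]), error = function(e) NA_real_)
    }, numeric(1))
    qs <- quantile(bs, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  } else {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    m <- matrix(c(sxx, sxy, sxy, syy), 2)
    l <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
    ratio <- l[1] / l[2] + l[2] / l[1] - 2
    H <- if (ratio <= 0) Inf else
      qf(ci_level, 1, n - 2) / (ratio * (n - 2))
    if (!is.finite(H) || 4 * H >= 1) {
      lo <- -Inf; hi <- Inf
    } else {
      dtheta <- asin(2 * sqrt(H)) / 2
      theta <- atan(b)
      lo <- tan(theta - dtheta)
      hi <- tan(theta + dtheta)
      # the slope angle lives on a half-circle: crossing the vertical makes
      # the interval unbounded on that side
      if (theta + dtheta >= pi / 2) hi <- Inf
      if (theta - dtheta <= -pi / 2) lo <- -Inf
    }
  }

  structure(list(slope = b, intercept = a, slope_ci_low = lo,
                 slope_ci_high = hi, n = n, r = r, ci_level = ci_level,
                 ci_method = ci_method),
            class = "ma_fit")
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf(
    "Major axis regression (n = %d)\n  slope = %.4f  [%g%% CI %.4f, %.4f]\n  intercept = %.4f   r = %.3f\n",
    x$n, x$slope, 100 * x$ci_level, x$slope_ci_low, x$slope_ci_high,
    x$intercept, x$r))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the per-species differences `a - b`
#' (untransformed km2 here), with the classic zero policy: zero differences
#' are dropped and `n_pairs` counts the remainder. The null distribution is
#' exact for `n_pairs <= 25` without ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' `zero_policy = "pratt"` instead ranks zeros before discarding their
#' ranks (normal approximation).
#'
#' @param a,b numeric vectors of equal length.
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @return list(`statistic`, `p_value`, `n_pairs`, `median_a`, `median_b`,
#'   `method`).
#' @export
paired_wilcoxon <- function(a, b, zero_policy = c("drop", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  if (length(a) != length(b) || length(a) < 1) {
    abort("a and b must be non-empty vectors of equal length",
          class = "natparadox_input_error")
  }
  d <- a - b
  if (zero_policy == "drop") {
    d <- d[d != 0]
    if (length(d) == 0) {
      abort("all paired differences are zero: no information",
            class = "natparadox_input_error")
    }
    ties <- any(duplicated(abs(d)))
    ht <- suppressWarnings(wilcox.test(
      d, alternative = "two.sided",
      exact = length(d) <= 25 && !ties, correct = TRUE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
    method <- if (length(d) <= 25 && !ties) "exact" else "normal_tie_corrected"
  } else {
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, n_pairs = 0,
                  median_a = median(a), median_b = median(b),
                  method = "pratt"))
    }
    # Pratt: rank |d| including zeros, then discard zero ranks
    rk <- rank(abs(d))
    keep <- d != 0
    stat <- sum(rk[keep & d > 0])
    n <- length(d)
    mu <- sum(rk[keep]) / 2
    sigma2 <- sum(rk[keep]^2) / 4
    z <- (stat - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    d <- d[keep]
    method <- "pratt"
  }
  list(statistic = stat, p_value = p, n_pairs = length(d),
       median_a = median(a), median_b = median(b), method = method)
}

#' Classify paradox species by range compensation
#'
#' For species that are both naturalized and threatened in part of their
#' native range, compares the naturalized AOO with the threatened native
#' AOO. A smaller naturalized range is partial compensation; a larger one is
#' a net increase. Exact ties form their own class and are excluded from the
#' two percentages, which therefore sum to 100.
#'
#' @param partitions tibble from [partition_aoo()], restricted upstream to
#'   paradox species; rows where either AOO is zero are excluded from
#'   classification and counted in `n_excluded_zero_aoo`.
#' @return list(`results` tibble with `species`, `aoo_naturalized`,
#'   `aoo_threatened`, `difference`, `klass`; `pct_partial`, `pct_net`,
#'   `n_tie`, `n_excluded_zero_aoo`, plus 1-decimal reported fields).
#' @export
classify_compensation <- function(partitions) {
  assert_columns(partitions, c("species", "aoo_naturalized",
                               "aoo_native_threatened"), "partition table")
  ok <- partitions$aoo_naturalized > 0 & partitions$aoo_native_threatened > 0
  df <- partitions[ok, ]
  diff <- df$aoo_naturalized - df$aoo_native_threatened
  klass <- dplyr::case_when(diff < 0 ~ "partial_compensation",
                            diff > 0 ~ "net_increase",
                            TRUE ~ "tie")
  res <- tibble::tibble(species = df$species,
                        aoo_naturalized = df$aoo_naturalized,
                        aoo_threatened = df$aoo_native_threatened,
                        difference = diff, klass = klass)
  n_nontie <- sum(klass != "tie")
  pct_partial <- if (n_nontie > 0) 100 * sum(klass == "partial_compensation") / n_nontie else NA_real_
  pct_net <- if (n_nontie > 0) 100 * sum(klass == "net_increase") / n_nontie else NA_real_
  list(results = res, pct_partial = pct_partial, pct_net = pct_net,
       pct_partial_reported = round_half_up(pct_partial, 1),
       pct_net_reported = round_half_up(pct_net, 1),
       n_tie = sum(klass == "tie"), n_excluded_zero_aoo = sum(!ok))
}

#' Bland-Altman agreement summary
#'
#' Per-species differences `a - b` against means, with limits of agreement
#' `mean(difference) +- 1.96 sd(difference)`. Used on log10 AOOs to
#' visualize how naturalized and threatened range sizes diverge.
#'
#' @param a,b numeric vectors (log10 km2), finite, equal length, n >= 2.
#' @return list(`mean_difference`, `limits` (length-2), `table` tibble with
#'   per-item `mean` and `difference`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2 ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    abort("a and b must be finite vectors of equal length, n >= 2",
          class = "natparadox_input_error")
  }
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  list(mean_difference = m, limits = c(m - 1.96 * s, m + 1.96 * s),
       table = tibble::tibble(mean = (a + b) / 2, difference = d))
}

#' Histogram summary of the percent of native AOO threatened
#'
#' Bins the per-species percentage at width 5 — `[0,5), [5,10), ...,
#' [95,100]` — and reports its mean and median. Species without a defined
#' percentage (no native occurrences) are excluded and counted.
#'
#' @param partitions tibble from [partition_aoo()].
#' @return list(`mean`, `median`, `bins` tibble (`bin_low`, `bin_high`,
#'   `count`), `n`, `n_excluded`).
#' @export
pct_threatened_histogram <- function(partitions) {
  assert_columns(partitions, "pct_native_threatened", "partition table")
  v <- partitions$pct_native_threatened
  n_excluded <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    abort("no species with a defined percentage",
          class = "natparadox_input_error")
  }
  lo <- seq(0, 95, by = 5)
  counts <- vapply(seq_along(lo), function(i) {
    if (i < length(lo)) sum(v >= lo[i] & v < lo[i] + 5)
    else sum(v >= lo[i] & v <= 100)
  }, integer(1))
  list(mean = mean(v), median = median(v),
       bins = tibble::tibble(bin_low = lo, bin_high = lo + 5, count = counts),
       n = length(v), n_excluded = n_excluded)
}
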