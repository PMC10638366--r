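test_result <- function(statistic, p, n1, n2 = NA_integer_, method) {
  structure(list(statistic = unname(statistic), p = unname(p),
                 n1 = n1, n2 = n2, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n1 = %d%s)\n", x$method,
              x$statistic, x$p, x$n1,
              if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

#' Ordinary least-squares simple linear regression
#'
#' Closed-form least squares of y on x with coefficient standard errors,
#' coefficient covariance, R-squared and the two-sided p-value of the
#' slope from the t distribution with n - 2 degrees of freedom (for
#' simple regression this equals the F-test p of the fit).
#'
#' @param x,y numeric vectors of equal length, n >= 3, var(x) > 0.
#' @return Object of class \code{regression_result}: slope, slope_se,
#'   intercept, intercept_se, r_squared, p_slope, n, residual_sd,
#'   coef_cov (2x2, intercept first).
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need n >= 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stopf("degenerate x: no variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  s2 <- rss / (n - 2)
  slope_se <- sqrt(s2 / sxx)
  intercept_se <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  cov_ab <- -s2 * mean(x) / sxx
  tstat <- slope / slope_se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(slope = slope, slope_se = slope_se,
                 intercept = intercept, intercept_se = intercept_se,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 p_slope = p, n = n, residual_sd = sqrt(s2),
                 coef_cov = matrix(c(intercept_se^2, cov_ab,
                                     cov_ab, slope_se^2), 2, 2,
                                   dimnames = list(c("intercept", "slope"),
                                                   c("intercept", "slope")))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<ols> y = %.4g (+/- %.2g) x + %.4g (+/- %.2g), R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$r_squared, x$p_slope, x$n))
  invisible(x)
}

#' Two-sample t test
#'
#' Two-sided Student's (pooled-variance) or Welch's t test.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant "student" (pooled variance) or "welch".
#' @return a test_result (statistic t, two-sided p, group sizes).
#' @export
t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stopf("each group needs n >= 2")
  d <- mean(a) - mean(b)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- var(a) / n1; v2 <- var(b) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- if (se > 0) d / se else 0
  p <- if (se > 0) 2 * pt(-abs(t), df) else 1
  res <- test_result(t, p, n1, n2,
                     if (variant == "student") "student_t" else "welch_t")
  res$df <- df
  res
}

# Null distribution of the rank-sum of a size-n1 subset of ranks 1..N:
# dynamic-programming count of subsets by size and sum.
ranksum_null_probs <- function(n1, N) {
  max_s <- sum((N - n1 + 1):N)
  # counts[k+1, s+1] = number of subsets of size k with sum s
  counts <- matrix(0, n1 + 1, max_s + 1)
  counts[1, 1] <- 1
  for (v in seq_len(N)) {
    for (k in min(n1, v):1) {
      shifted <- c(rep(0, v), counts[k, seq_len(max_s + 1 - v)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  counts[n1 + 1, ] / choose(N, n1)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test; the statistic W is the sum of the ranks of
#' the first group in the pooled sample. Small tie-free samples (combined
#' n at most \code{exact_limit}) use the exact null distribution of the
#' rank-sum; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric vectors, each of length >= 1.
#' @param exact_limit combined-size threshold for the exact path.
#' @return a test_result (statistic W, two-sided p, method
#'   "wilcoxon_exact" or "wilcoxon_normal").
#' @export
wilcoxon_test <- function(a, b, exact_limit = 20L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stopf("each group needs n >= 1")
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  ties <- any(duplicated(pooled))
  if (!ties && N <= exact_limit) {
    probs <- ranksum_null_probs(n1, N)
    sums <- seq_along(probs) - 1
    p_le <- sum(probs[sums <= W])
    p_ge <- sum(probs[sums >= W])
    p <- min(1, 2 * min(p_le, p_ge))
    return(test_result(W, p, n1, n2, "wilcoxon_exact"))
  }
  mu <- n1 * (N + 1) / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  p <- min(1, 2 * pnorm(-abs(z)))
  test_result(W, p, n1, n2, "wilcoxon_normal")
}

#' Shapiro-Wilk normality test
#'
#' W statistic from the standard approximation to the expected normal
#' order-statistic coefficients, with the polynomial corrections to the
#' two outermost weights; p-value from the standard normalizing
#' transformation of 1 - W (log-normal regimes for n in 4..11 and
#' n >= 12; exact for n = 3).
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return a test_result (statistic W, p, method "shapiro_wilk").
#' @export
shapiro_wilk <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3L || n > 5000L) stopf("n must be in [3, 5000] (got %d)", n)
  if (diff(range(x)) == 0) stopf("all observations are identical")
  m <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssm <- sum(m^2)
  a <- m / sqrt(ssm)
  if (n > 3L) {
    rsn <- 1 / sqrt(n)
    an <- a[n] + (-2.706056 * rsn^5 + 4.434685 * rsn^4 - 2.071190 * rsn^3
                  - 0.147981 * rsn^2 + 0.221157 * rsn)
    if (n > 5L) {
      an1 <- a[n - 1] + (-3.582633 * rsn^5 + 5.682633 * rsn^4
                         - 1.752461 * rsn^3 - 0.293762 * rsn^2
                         + 0.042981 * rsn)
      phi <- (ssm - 2 * m[n]^2 - 2 * m[n - 1]^2) /
        (1 - 2 * an^2 - 2 * an1^2)
      a <- m / sqrt(phi)
      a[c(1, n)] <- c(-an, an)
      a[c(2, n - 1)] <- c(-an1, an1)
    } else {
      phi <- (ssm - 2 * m[n]^2) / (1 - 2 * an^2)
      a <- m / sqrt(phi)
      a[c(1, n)] <- c(-an, an)
    }
  }
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)
  if (n == 3L) {
    p <- max(0, min(1, 6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))))
  } else if (n <= 11L) {
    gam <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    z <- (-log(gam - log(1 - W)) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    z <- (log(1 - W) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  }
  test_result(W, max(p, .Machine$double.xmin), n, NA_integer_,
              "shapiro_wilk")
}

#' Manual-vs-automated pore-count agreement
#'
#' Per-specimen relative difference 100 * |manual - auto| / manual (the
#' manual count is the reference), with its mean and range, and a t test
#' comparing the manual and automated mean pore densities. Both the
#' unpaired comparison of the two group means and the natural paired
#' variant are reported.
#'
#' @param manual_counts,auto_counts pore counts per specimen (> 0
#'   manual).
#' @param roi_areas measured areas per specimen, square micrometers.
#' @return Object of class \code{agreement_report}: per_specimen table,
#'   mean_diff_pct, range_pct, mean PDs, t_unpaired and t_paired test
#'   results.
#' @export
manual_auto_agreement <- function(manual_counts, auto_counts, roi_areas) {
  n <- length(manual_counts)
  if (length(auto_counts) != n || length(roi_areas) != n)
    stopf("manual_counts, auto_counts and roi_areas must have equal length")
  if (any(manual_counts <= 0))
    stopf("manual counts must be positive (reference method)")
  diff_pct <- 100 * abs(manual_counts - auto_counts) / manual_counts
  pd_manual <- manual_counts / roi_areas
  pd_auto <- auto_counts / roi_areas
  d <- pd_manual - pd_auto
  if (n < 2L) {
    t_un <- t_pa <- test_result(NA_real_, NA_real_, n, n, "student_t")
  } else {
  t_un <- t_test(pd_manual, pd_auto, "student")
  if (sd(d) > 0) {
    tp <- mean(d) / (sd(d) / sqrt(n))
    t_pa <- test_result(tp, 2 * pt(-abs(tp), n - 1), n, n, "paired_t")
  } else {
    t_pa <- test_result(0, 1, n, n, "paired_t")
  }
  }
  structure(list(
    per_specimen = data.frame(specimen = seq_len(n),
                              manual = manual_counts, auto = auto_counts,
                              roi_area_um2 = roi_areas,
                              pd_manual = pd_manual, pd_auto = pd_auto,
                              diff_pct = diff_pct),
    mean_diff_pct = mean(diff_pct),
    range_pct = range(diff_pct),
    pd_manual_mean = mean(pd_manual),
    pd_auto_mean = mean(pd_auto),
    t_unpaired = t_un, t_paired = t_pa),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n = %d, mean difference %.1f%% ",
                     "(range %.1f-%.1f%%), mean PD manual %.4g vs auto %.4g ",
                     "(t = %.2f, p = %.2g)\n"),
              nrow(x$per_specimen), x$mean_diff_pct, x$range_pct[1],
              x$range_pct[2], x$pd_manual_mean, x$pd_auto_mean,
              x$t_unpaired$statistic, x$t_unpaired$p))
  invisible(x)
}
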