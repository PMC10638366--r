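test_that("OLS matches the normal-equations solve and base R on fixtures", {
  f <- ols_fit(1:4, 2 * (1:4) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- rnorm(1, sd = 2) * x + rnorm(1) + rnorm(n)
    f <- ols_fit(x, y)
    # independent oracle: direct normal-equations matrix solve
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_lt(abs(f$intercept - beta[1]), 1e-10)
    expect_lt(abs(f$slope - beta[2]), 1e-10)
  }
  # cross-check SEs, R^2 and p against base R lm on one fixture
  set.seed(7)
  x <- rnorm(25); y <- 1.5 * x + rnorm(25)
  f <- ols_fit(x, y)
  s <- summary(lm(y ~ x))
  expect_equal(f$slope_se, coef(s)[2, 2])
  expect_equal(f$intercept_se, coef(s)[1, 2])
  expect_equal(f$r_squared, s$r.squared)
  expect_equal(f$p_slope, coef(s)[2, 4])
  expect_equal(f$coef_cov, vcov(lm(y ~ x)), ignore_attr = TRUE)

  expect_error(ols_fit(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(ols_fit(1:3, 1:4), "lengths differ")
  expect_error(ols_fit(1:2, 1:2), "n >= 3")
})

test_that("t tests match their closed forms and are affine invariant", {
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  tt <- t_test(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(tt$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)

  set.seed(5)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  for (variant in c("student", "welch")) {
    mine <- t_test(a, b, variant)
    ref <- t.test(a, b, var.equal = variant == "student")
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
    # common affine transform of both groups leaves t and p unchanged
    shifted <- t_test(3 * a - 2, 3 * b - 2, variant)
    expect_equal(shifted$statistic, mine$statistic, tolerance = 1e-12)
    expect_equal(shifted$p, mine$p, tolerance = 1e-12)
  }
  expect_error(t_test(1, c(1, 2)), "n >= 2")
})

test_that("exact Wilcoxon equals full enumeration for all small tie-free inputs", {
  w <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_equal(w$statistic, 3)
  expect_equal(w$p, 1 / 3)
  expect_identical(w$method, "wilcoxon_exact")
  w2 <- wilcoxon_test(c(1, 4), c(2, 3))
  expect_equal(w2$statistic, 5)
  expect_equal(w2$p, 1)

  # exhaustive: every split and every assignment of ranks 1..N, N <= 10,
  # against a combn enumeration oracle
  for (N in 3:10) {
    for (n1 in 1:(N - 1)) {
      subsets <- combn(N, n1)
      null_sums <- colSums(matrix(subsets, nrow = n1))
      for (j in seq_len(ncol(subsets))) {
        a <- subsets[, j]
        b <- setdiff(1:N, a)
        got <- wilcoxon_test(a, b)
        W <- sum(a)
        p_oracle <- min(1, 2 * min(mean(null_sums <= W),
                                   mean(null_sums >= W)))
        expect_identical(got$method, "wilcoxon_exact")
        expect_equal(got$p, p_oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("large samples and ties use the corrected normal approximation", {
  set.seed(42)
  a <- rnorm(30); b <- rnorm(35, 0.4)
  mine <- wilcoxon_test(a, b)
  expect_identical(mine$method, "wilcoxon_normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # W is the rank sum of the first group (R reports the Mann-Whitney U)
  expect_equal(mine$statistic - 30 * 31 / 2, unname(ref$statistic))

  # ties force the normal path even for small samples
  tied <- wilcoxon_test(c(1, 2, 2), c(2, 3))
  expect_identical(tied$method, "wilcoxon_normal")
  tref <- wilcox.test(c(1, 2, 2), c(2, 3), exact = FALSE, correct = TRUE)
  expect_equal(tied$p, tref$p.value, tolerance = 1e-12)

  # p is invariant under common strictly monotone transforms
  expect_equal(wilcoxon_test(exp(a), exp(b))$p, mine$p)

  # normal approximation tracks a permutation oracle
  set.seed(9)
  x <- rnorm(40); y <- rnorm(45, 0.3)
  obs <- wilcoxon_test(x, y)
  pooled <- c(x, y)
  mu <- 40 * 86 / 2
  perm <- replicate(10000, {
    idx <- sample.int(85, 40)
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(abs(perm - mu) >= abs(obs$statistic - mu))
  expect_lt(abs(obs$p - p_perm), 0.01)
})

test_that("Shapiro-Wilk reproduces the reference W and p", {
  expect_error(shapiro_wilk(c(1, 2)), "n must be in")
  set.seed(3)
  x10 <- rnorm(10)
  expect_lt(abs(shapiro_wilk(x10)$statistic - shapiro.test(x10)$statistic),
            1e-3)
  for (n in c(5, 12, 30, 200)) {
    x <- rnorm(n, 2, 3)
    mine <- shapiro_wilk(x)
    ref <- shapiro.test(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-4)
  }
  # clearly non-normal data is rejected
  expect_lt(shapiro_wilk(rexp(100))$p, 0.01)
})

test_that("manual-vs-automated agreement report follows its definitions", {
  same <- manual_auto_agreement(c(100, 200), c(100, 200), c(5e4, 6e4))
  expect_equal(same$mean_diff_pct, 0)
  expect_equal(same$t_unpaired$p, 1)

  r <- manual_auto_agreement(100, 90, 5e4)
  expect_equal(r$per_specimen$diff_pct, 10)

  expect_error(manual_auto_agreement(c(0, 10), c(1, 9), c(1, 1)),
               "positive")

  # close agreement (small symmetric count perturbations) gives a tiny
  # mean difference and an indistinguishable mean PD
  set.seed(11)
  manual <- rpois(31, 300)
  auto <- manual + sample(c(-8:8), 31, replace = TRUE)
  areas <- runif(31, 5e4, 7e4)
  rep31 <- manual_auto_agreement(manual, auto, areas)
  expect_lt(rep31$mean_diff_pct, 5)
  expect_gt(rep31$t_unpaired$p, 0.5)
  expect_true(all(rep31$per_specimen$diff_pct >= 0))
})
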