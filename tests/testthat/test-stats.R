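test_that("Pearson correlation matches hand product-moment computation", {
  x <- 1:10
  expect_equal(cor_pearson(x, x)$r, 1)
  expect_lt(cor_pearson(x, x + 0)$p, 1e-10)
  expect_equal(cor_pearson(x, -x)$r, -1)
  # hand computation: sum(dx*dy) = 3, sqrt(5*5) = 5 -> r = 0.6
  h <- cor_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(h$r, 0.6)
  expect_equal(h$r_squared, 0.36)
  expect_error(cor_pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(cor_pearson(1:2, 2:3), "at least 3")
})

test_that("Spearman correlation works on ranks with mid-rank ties", {
  x <- 1:8
  expect_equal(cor_spearman(x, x^3)$rho, 1)       # monotone nonlinear
  expect_equal(cor_spearman(x, rev(x))$rho, -1)
  expect_equal(cor_spearman(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_silent(cor_spearman(c(1, 2, 2, 4, 5), c(2, 2, 3, 3, 1)))  # ties ok
})

test_that("Shapiro-Wilk gate separates normal from skewed samples", {
  set.seed(202)
  norm_keep <- replicate(100, shapiro_wilk(rnorm(200))$p >= 0.05)
  expect_gte(mean(norm_keep), 0.90)
  exp_reject <- replicate(100, shapiro_wilk(rexp(200))$p < 0.05)
  expect_gte(mean(exp_reject), 0.95)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("signed-rank V takes its extreme values on strictly ordered pairs", {
  set.seed(5)
  y <- rnorm(12)
  up <- wilcoxon_signed_rank(y + seq(0.5, 2, length.out = 12), y)
  expect_equal(up$statistic, 78)   # all positive: V = 12*13/2
  down <- wilcoxon_signed_rank(y - seq(0.5, 2, length.out = 12), y)
  expect_equal(down$statistic, 0)
  expect_equal(up$p, down$p)       # mirror-image data, same two-sided p

  # d = (+1, -2, +3): ranks (1,2,3), V = 1 + 3 = 4, exact p = 0.75
  r <- wilcoxon_signed_rank(c(1, -2, 3), c(0, 0, 0))
  expect_equal(r$statistic, 4)
  expect_equal(r$p, 0.75)

  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "non-zero")
})

test_that("wilcoxon exact p equals full sign-vector enumeration (n <= 12)", {
  set.seed(31)
  for (n in c(5, 8, 12)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 3)
      got <- wilcoxon_signed_rank(d, rep(0, n))
      expect_equal(got$statistic, enum_wilcoxon_v(d))
      expect_equal(got$p, enum_wilcoxon_p(d), tolerance = 1e-12)
    }
  }
})

test_that("V plus its sign-flipped counterpart is n(n+1)/2 on tie-free data", {
  set.seed(17)
  for (n in c(6, 9, 15)) {
    d <- rnorm(n)
    v1 <- wilcoxon_signed_rank(d, rep(0, n))$statistic
    v2 <- wilcoxon_signed_rank(-d, rep(0, n))$statistic
    expect_equal(v1 + v2, n * (n + 1) / 2)
  }
})

test_that("paired t-test: hand formula, shift invariance, degenerate guard", {
  r <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$statistic, 2 * sqrt(3))  # mean 2, sd 1, sqrt(3)
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(paired_t(x, y)$statistic, paired_t(x + 5, y + 5)$statistic)
  expect_error(paired_t(c(1, 2, 3, 4), c(0, 1, 2, 3)), "zero-variance")
})

test_that("the normality gate routes to t or wilcoxon as computed", {
  set.seed(77)
  y <- rnorm(20)
  near_normal <- paired_contrast(y + rnorm(20, 0.5, 0.3), y)
  expect_equal(near_normal$test_kind,
               if (near_normal$normality_p >= 0.05) "t" else "wilcoxon")
  expect_equal(near_normal$test_kind, "t")
  heavy <- paired_contrast(y + rexp(20)^3, y)
  expect_equal(heavy$test_kind, "wilcoxon")
  expect_lt(heavy$normality_p, 0.05)
  expect_error(paired_contrast(c(1, 2), c(0, 1)), "at least 3")
})

test_that("OLS: exact fits, null fits, and the hand-solved normal equations", {
  d <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  m <- suppressWarnings(ols_fit(y ~ x, d))
  expect_equal(max(abs(m$residuals)), 0, tolerance = 1e-12)
  expect_equal(m$adj_r_squared, 1)
  expect_equal(m$coefficients$estimate, c(2, 3))

  set.seed(9)
  d2 <- data.frame(x = rnorm(100), y = rnorm(100))
  m2 <- ols_fit(y ~ x, d2)
  expect_lt(abs(m2$coefficients$estimate[2]), 0.25)
  expect_lte(m2$adj_r_squared, 0.05)

  # 4-point system solved by hand via the normal equations:
  # x = (0,1,2,3), y = (1,2,2,4): slope = Sxy/Sxx = 4.5/5 = 0.9, intercept 0.9
  m3 <- ols_fit(y ~ x, data.frame(x = 0:3, y = c(1, 2, 2, 4)))
  expect_equal(m3$coefficients$estimate, c(0.9, 0.9))

  expect_error(ols_fit(y ~ x + I(2 * x), data.frame(x = 1:5, y = rnorm(5))),
               "rank")
  expect_error(ols_fit(y ~ x1 + x2 + x3,
                       data.frame(x1 = 1:3, x2 = c(2, 1, 5), x3 = c(3, 3, 1),
                                  y = rnorm(3))),
               "more observations")
})

test_that("simple regression ties out against the correlation coefficient", {
  set.seed(21)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ct <- cor_pearson(x, y)
  m <- ols_fit(y ~ x, data.frame(x = x, y = y))
  expect_equal(m$coefficients$estimate[2], ct$r * sd(y) / sd(x))
  expect_equal(m$r_squared, ct$r_squared)
})

test_that("Cook's distance: closed form equals leave-one-out refits", {
  set.seed(4)
  for (rep in 1:3) {
    d <- data.frame(x = rnorm(15), z = rnorm(15))
    d$y <- 1 + 0.5 * d$x - 0.3 * d$z + rnorm(15)
    m <- ols_fit(y ~ x * z, d)
    expect_lt(max(abs(m$cooks - loo_cooks(m$fit))), 1e-10)
    expect_equal(unname(m$cooks), unname(stats::cooks.distance(m$fit)))
  }

  # perfect fit: all distances zero
  mp <- suppressWarnings(ols_fit(y ~ x, data.frame(x = 1:6, y = 2 * (1:6))))
  expect_equal(max(mp$cooks), 0, tolerance = 1e-12)

  # one gross outlier in an otherwise linear n = 12 set dominates and exceeds 1
  d <- data.frame(x = 1:12, y = 1:12 + rnorm(12, 0, 0.05))
  d$x[12] <- 30; d$y[12] <- -20
  mo <- ols_fit(y ~ x, d)
  expect_equal(which.max(mo$cooks), c(`12` = 12L))
  expect_gt(max(mo$cooks), 1)
  expect_equal(mo$influential, "12")
})
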