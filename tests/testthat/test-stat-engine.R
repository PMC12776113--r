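test_that("exact binomial test reproduces the reference analysis p-values", {
  expect_equal(round(binom_test_exact(23, 37, 0.5), 2), 0.19)
  expect_equal(signif(binom_test_exact(44, 53, 0.5), 3), 1.22e-6)
  expect_equal(signif(binom_test_exact(37, 45, 53 / 55), 3), 1.97e-4)
})

test_that("exact binomial test handles degenerate and invalid inputs", {
  expect_equal(binom_test_exact(5, 5, 1), 1)
  expect_equal(binom_test_exact(0, 7, 0), 1)
  expect_error(binom_test_exact(6, 5, 0.5), "x <= n")
  expect_error(binom_test_exact(2, 5, 1.2), "p0")
  expect_error(binom_test_exact(2.5, 5, 0.5), "integers")
})

test_that("exact binomial test matches brute-force outcome enumeration", {
  for (n in c(3L, 7L, 11L)) {
    for (p0 in c(0.1, 0.5, 53 / 55)) {
      for (x in 0:n) {
        expect_equal(binom_test_exact(x, n, p0), binom_enum_oracle(x, n, p0),
                     tolerance = 1e-12,
                     label = sprintf("binom(x=%d, n=%d, p0=%.3f)", x, n, p0))
      }
    }
  }
})

test_that("binomial p-values are symmetric and monotone under a fair null", {
  for (n in c(10L, 37L, 53L)) {
    p <- vapply(0:n, binom_test_exact, numeric(1), n = n, p0 = 0.5)
    expect_equal(p, rev(p))                         # symmetry x <-> n - x
    upper <- p[(floor(n / 2) + 1 + (n %% 2)):(n + 1)]
    expect_true(all(diff(upper) <= 1e-12))          # non-increasing in |x - n/2|
  }
})

test_that("exact binomial test holds its size under a simulated null", {
  set.seed(123)
  n <- 50L
  pvals_by_x <- vapply(0:n, binom_test_exact, numeric(1), n = n, p0 = 0.5)
  draws <- stats::rbinom(1000, n, 0.5)
  rate <- mean(pvals_by_x[draws + 1] < 0.05)
  # exact tests are conservative: at most alpha plus 3 binomial SEs
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Mann-Whitney test reproduces hand-computable cases", {
  same <- mann_whitney(1:5, 1:5)
  expect_equal(same$u_statistic, 12.5)
  expect_equal(same$p_value, 1)

  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)
  expect_equal(sep$p_value, 0.1)   # 2 of the 20 labelings are as extreme
  expect_identical(sep$method, "exact")
})

test_that("Mann-Whitney U statistics from midranks are complementary", {
  set.seed(11)
  for (i in 1:25) {
    a <- sample(1:6, sample(2:12, 1), replace = TRUE)   # ties likely
    b <- rnorm(sample(2:12, 1))
    ua <- mann_whitney(a, b, mode = "approx")$u_statistic
    ub <- mann_whitney(b, a, mode = "approx")$u_statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact Mann-Whitney mode agrees with complete labeling enumeration", {
  set.seed(21)
  for (m in c(2L, 4L, 7L)) {
    for (n in c(3L, 6L, 8L)) {
      a <- rnorm(m)
      b <- rnorm(n, mean = 0.5)
      got <- mann_whitney(a, b, mode = "exact")
      want <- mw_enum_oracle(a, b)
      expect_equal(got$u_statistic, want$u)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  }
})

test_that("exact and approximate Mann-Whitney p-values agree at n = 10", {
  set.seed(31)
  diffs <- replicate(500, {
    a <- rnorm(10)
    b <- rnorm(10, mean = runif(1, -1, 1))
    abs(mann_whitney(a, b, mode = "exact")$p_value -
          mann_whitney(a, b, mode = "approx")$p_value)
  })
  expect_gte(mean(diffs < 0.01), 0.95)
})

test_that("Mann-Whitney matches the reference implementation on random data", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(4:9, 1))
    b <- rnorm(sample(4:9, 1))
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  for (i in 1:20) {
    a <- sample(1:8, 30, replace = TRUE)   # ties force the approximation
    b <- sample(1:9, 25, replace = TRUE)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    got <- mann_whitney(a, b)
    expect_identical(got$method, "normal_approx")
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney rejects empty samples and warns on tied exact mode", {
  expect_error(mann_whitney(numeric(0), 1:3), "sample_a")
  expect_error(mann_whitney(1:3, c(NA_real_, NA_real_)), "sample_b")
  expect_warning(mann_whitney(c(1, 1, 2), c(2, 3, 4), mode = "exact"),
                 "ties")
})

test_that("log transforms exclude per the transform's domain", {
  lp <- apply_transform(c(0, 9, 99), "log10_plus1")
  expect_equal(lp$values, c(0, 1, 2))
  expect_equal(lp$n_excluded, 0)

  lr <- apply_transform(c(0.1, 0, NA), "log10_ratio")
  expect_equal(lr$values, -1)
  expect_equal(lr$n_excluded, 2)

  expect_equal(apply_transform(c(10, 100), "log10_raw")$values, c(1, 2))
  expect_equal(apply_transform(c(5, NA, 7), "log10_plus1")$n_excluded, 1)
})

test_that("star labels follow strict significance thresholds", {
  expect_identical(star_label(c(0.0005, 0.005, 0.03, 0.05, 0.2, 1)),
                   c("***", "**", "*", "ns", "ns", "ns"))
  expect_identical(star_label(c(0.001, 0.01)), c("**", "*"))
  expect_error(star_label(0))
})
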