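test_that("pearson_test matches brute-force covariance arithmetic", {
  x <- 1:5
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1.0)

  toy_x <- c(2, 5, 1, 4)
  toy_y <- c(9, 3, 8, 4)
  res <- pearson_test(toy_x, toy_y)
  ref <- pearson_brute(toy_x, toy_y)
  expect_equal(res$r, ref$r)
  expect_equal(res$p, ref$p)
  expect_identical(res$n, 4L)

  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    res <- pearson_test(x, y)
    ref <- pearson_brute(x, y)
    expect_equal(res$r, ref$r)
    expect_equal(res$p, ref$p)
  }
})

test_that("pearson_test handles degenerate and incomplete input", {
  expect_warning(res <- pearson_test(1:5, rep(3, 5)), "zero variance")
  expect_true(is.na(res$r))
  expect_warning(pearson_test(1:2, 2:1), "fewer than 3")
  # pairwise deletion
  res <- pearson_test(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_identical(res$n, 3L)
  expect_equal(res$r, 1.0)
})

test_that("partial correlation equals Pearson on normal-equation residuals", {
  set.seed(77)
  for (i in 1:10) {
    n <- 6 + i
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_correlation(x, y, z)
    ref <- partial_r_brute(x, y, z)
    expect_equal(res$r, ref$r)
    expect_equal(res$p, ref$p)
  }
})

test_that("partial correlation degenerates sensibly", {
  z <- rnorm(10)
  # both variables identical to the covariate: residuals vanish
  expect_warning(res <- partial_correlation(z, z, z), "fully explained")
  expect_true(is.na(res$r))
  # covariate orthogonal in-sample: partial r equals plain r
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12); zc <- rnorm(12)
  zo <- resid(lm(zc ~ x + y)) # orthogonal to both by construction
  expect_equal(partial_correlation(x, y, zo)$r,
               cor(resid(lm(x ~ zo)), resid(lm(y ~ zo))))
  # zero-variance covariate falls back to plain Pearson
  expect_warning(res <- partial_correlation(x, y, rep(1, 12)),
                 "plain Pearson")
  expect_equal(res$r, pearson_test(x, y)$r)
})

test_that("BH control reproduces the step-up rule", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(res$significant))
  expect_false(any(bh_fdr(rep(1, 6), 0.05)$significant))
  expect_true(bh_fdr(0.049, 0.05)$significant)
  expect_false(bh_fdr(0.051, 0.05)$significant)
  expect_identical(nrow(bh_fdr(numeric(0))), 0L)
  expect_error(bh_fdr(c(0.2, NA)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    delta <- runif(1, 0.01, 0.2)
    res <- bh_fdr(p, delta)
    expect_identical(res$significant, bh_brute(p, delta))
    expect_true(all(res$significant == (res$p_adjusted <= delta)))
  }
})

test_that("independent t test matches the pooled-variance formula", {
  res <- independent_t(c(1, 2, 3), c(4, 5, 6))
  # hand pooled-variance arithmetic: sp2 = 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3))
  expect_equal(res$df, 4)
  expect_equal(res$mean_glucose, 2)
  expect_equal(res$mean_sucralose, 5)
  expect_lte(res$ci_low, res$ci_high)

  same <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(independent_t(c(1, 1, 1), c(2, 2, 2)), "unbounded")
  expect_error(independent_t(1, c(2, 3)), "at least 2")
})

test_that("the Levene gate matches car's mean-centered test", {
  set.seed(6)
  x <- rnorm(15, 0, 1); y <- rnorm(15, 1, 3)
  res <- independent_t(x, y)
  g <- factor(rep(c("a", "b"), each = 15))
  ref <- car::leveneTest(c(x, y) ~ g, center = "mean")[1, "Pr(>F)"]
  expect_equal(res$levene_p, ref)
})

test_that("chi-square on 2x2 tables", {
  prop <- matrix(c(10, 20, 5, 10), 2) # perfectly proportional rows
  expect_equal(chi_square_2x2(prop)$statistic, 0)
  diag <- matrix(c(10, 0, 0, 10), 2)
  res <- chi_square_2x2(diag)
  expect_equal(res$statistic, 20)
  expect_equal(res$n, 20)
  expect_warning(res0 <- chi_square_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)),
                 "marginal") # zero row
  expect_true(is.na(res0$statistic))
  expect_warning(res0 <- chi_square_2x2(matrix(c(1, 2, 0, 0), 2)),
                 "marginal") # zero column
  expect_true(is.na(res0$statistic))
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("median split dichotomises with ties going low", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("LOW", "LOW", "HIGH", "HIGH"))
  expect_identical(as.character(median_split(c(1, 2, 2, 3))),
                   c("LOW", "LOW", "LOW", "HIGH"))
  expect_error(median_split(rep(2, 5)), "identical")
})

test_that("Cook's policy flags by threshold and replaces with the clean mean", {
  # exact line: zero residuals, nothing flagged
  x <- 1:10
  res <- cooks_outlier_policy(2 * x + 3, x)
  expect_identical(res$replaced_ids, character(0))
  expect_equal(res$y, 2 * x + 3)

  # tight cloud plus one gross outlier: flagged under both modes
  set.seed(10)
  x <- rnorm(20, 10, 2)
  y <- 3 + 0.5 * x + rnorm(20, 0, 0.2)
  xo <- c(x, 25); yo <- c(y, 2)
  ids <- sprintf("P%02d", 1:21)
  for (mode in c("4overN", "0.2")) {
    res <- cooks_outlier_policy(yo, xo, mode = mode, ids = ids)
    expect_identical(res$replaced_ids, "P21")
    expect_equal(res$y[21], mean(yo[1:20]))
    expect_identical(res$y[1:20], yo[1:20])
  }

  # agreement with direct Cook's distance and the leave-one-out oracle
  res <- cooks_outlier_policy(yo, xo)
  expect_equal(res$cooks_d, unname(cooks.distance(lm(yo ~ xo))))
  expect_equal(res$cooks_d, cooks_brute(yo, xo), tolerance = 1e-8)

  # fixed 0.2 mode replaces nothing when max D stays below 0.2
  set.seed(11)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30, 0, 1)
  d <- cooks_brute(y2, x2)
  stopifnot(max(d) < 0.2) # fixture property
  res <- cooks_outlier_policy(y2, x2, mode = "0.2")
  expect_identical(res$replaced_ids, character(0))

  # degenerate predictor: warn, flag nothing
  expect_warning(res <- cooks_outlier_policy(rnorm(6), rep(1, 6)),
                 "zero-variance")
  expect_identical(res$replaced_ids, character(0))
})
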