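test_that("two-level mixed ANCOVA matches the independent Type III oracle", {
  for (seed in c(1, 2, 3)) {
    fx <- random_ancova_fixture(n = 16 + 2 * seed, p = 2, seed = seed)
    res <- rm_ancova_2level(fx$Y[, 1], fx$Y[, 2], fx$group, fx$covariate)
    ref <- ancova_oracle(fx$Y, fx$group, fx$covariate)
    pick <- function(eff) res[res$effect == eff, ]
    expect_equal(pick("Taste")$ss, ref$time$ss, tolerance = 1e-8)
    expect_equal(pick("Taste:Drink")$ss, ref$time_group$ss, tolerance = 1e-8)
    expect_equal(pick("Taste:Covariate")$ss, ref$time_cov$ss,
                 tolerance = 1e-8)
    expect_equal(pick("Taste:Drink:Covariate")$ss, ref$time_group_cov$ss,
                 tolerance = 1e-8)
    expect_equal(pick("Drink")$ss, ref$group$ss, tolerance = 1e-8)
    expect_equal(pick("Covariate")$ss, ref$cov$ss, tolerance = 1e-8)
    expect_equal(pick("Drink:Covariate")$ss, ref$group_cov$ss,
                 tolerance = 1e-8)
    expect_equal(pick("Taste")$F, ref$time$f, tolerance = 1e-8)
    expect_equal(pick("Taste:Drink:Covariate")$F, ref$time_group_cov$f,
                 tolerance = 1e-8)
    expect_equal(pick("Drink")$F, ref$group$f, tolerance = 1e-8)
    # partial eta squared from its defining SS ratio
    expect_equal(pick("Taste")$partial_eta_sq,
                 ref$time$ss / (ref$time$ss + ref$time$err),
                 tolerance = 1e-8)
  }
})

test_that("four-level mixed ANCOVA matches the oracle, sphericity assumed", {
  for (seed in c(4, 5, 6)) {
    fx <- random_ancova_fixture(n = 18 + 2 * (seed - 4), p = 4, seed = seed)
    res <- rm_ancova_4level(fx$Y, fx$group, fx$covariate)
    ref <- ancova_oracle(fx$Y, fx$group, fx$covariate)
    pick <- function(eff) res[res$effect == eff, ]
    expect_equal(pick("Time")$ss, ref$time$ss, tolerance = 1e-8)
    expect_equal(pick("Time:Drink")$ss, ref$time_group$ss, tolerance = 1e-8)
    expect_equal(pick("Time:Covariate")$ss, ref$time_cov$ss,
                 tolerance = 1e-8)
    expect_equal(pick("Time:Drink:Covariate")$ss, ref$time_group_cov$ss,
                 tolerance = 1e-8)
    expect_equal(pick("Time")$F, ref$time$f, tolerance = 1e-8)
    expect_equal(pick("Time:Drink")$F, ref$time_group$f, tolerance = 1e-8)
    expect_equal(pick("Time")$df1, ref$time$df1)
    expect_equal(pick("Time")$df2, ref$time$df2)
    expect_equal(pick("Drink")$ss, ref$group$ss, tolerance = 1e-8)
    expect_equal(pick("Covariate")$F, ref$cov$f, tolerance = 1e-8)
  }
})

test_that("a pure time-by-group crossover is recovered exactly", {
  set.seed(30)
  n <- 20
  group <- rep(c("glucose", "sucralose"), each = n / 2)
  covariate <- rnorm(n, 15, 4)
  base <- rnorm(n, 50, 5)
  slope <- ifelse(group == "glucose", -1, 1) * 5
  Y <- sapply(0:3, function(j) base + slope * j + rnorm(n, 0, 1))
  res <- rm_ancova_4level(Y, group, covariate)
  ref <- ancova_oracle(Y, group, covariate)
  expect_equal(res$F[res$effect == "Time:Drink"], ref$time_group$f,
               tolerance = 1e-8)
  expect_lt(res$p[res$effect == "Time:Drink"], 1e-6)
})

test_that("degrees of freedom follow the (1, n-4) and (3, 3(n-4)) structure", {
  fx62 <- random_ancova_fixture(n = 62, p = 4, seed = 7)
  res <- rm_ancova_4level(fx62$Y, fx62$group, fx62$covariate)
  within <- grepl("^Time", res$effect)
  expect_true(all(res$df1[within] == 3))
  expect_true(all(res$df2[within] == 174))
  expect_true(all(res$df1[!within] == 1))
  expect_true(all(res$df2[!within] == 58))

  fx2 <- random_ancova_fixture(n = 62, p = 2, seed = 8)
  res2 <- rm_ancova_2level(fx2$Y[, 1], fx2$Y[, 2], fx2$group, fx2$covariate)
  expect_true(all(res2$df1 == 1))
  expect_true(all(res2$df2 == 58))
})

test_that("no within-subject change means a zero within F", {
  fx <- random_ancova_fixture(n = 12, p = 2, seed = 9)
  res <- rm_ancova_2level(fx$Y[, 1], fx$Y[, 1], fx$group, fx$covariate)
  expect_equal(res$F[res$effect == "Taste"], 0)
  expect_equal(res$partial_eta_sq[res$effect == "Taste"], 0)

  Yflat <- matrix(rep(rnorm(10, 40, 5), 4), ncol = 4)
  resf <- rm_ancova_4level(Yflat, rep(c("glucose", "sucralose"), 5),
                           rnorm(10))
  expect_equal(resf$F[resf$effect == "Time"], 0)
})

test_that("all F statistics are invariant to adding a constant everywhere", {
  fx <- random_ancova_fixture(n = 14, p = 4, seed = 10)
  res1 <- rm_ancova_4level(fx$Y, fx$group, fx$covariate)
  res2 <- rm_ancova_4level(fx$Y + 17.3, fx$group, fx$covariate)
  expect_equal(res1$F, res2$F, tolerance = 1e-9)
})

test_that("a difference score driven by the covariate shows up as Taste:Covariate", {
  set.seed(55)
  n <- 20
  group <- rep(c("glucose", "sucralose"), 10)
  covariate <- rnorm(n, 20, 6)
  before <- rnorm(n, 50, 2)
  shift <- ifelse(covariate > median(covariate), 10, -10)
  after <- before + shift + rnorm(n, 0, 1)
  res <- rm_ancova_2level(before, after, group, covariate)
  pcov <- res$p[res$effect == "Taste:Covariate"]
  expect_lt(pcov, 0.05)
  expect_equal(which.max(res$partial_eta_sq[grepl("^Taste", res$effect)]),
               which(res$effect[grepl("^Taste", res$effect)] ==
                       "Taste:Covariate"))
})

test_that("incomplete subjects are dropped with a warning", {
  fx <- random_ancova_fixture(n = 12, p = 4, seed = 11)
  Y <- fx$Y
  Y[3, 2] <- NA
  expect_warning(res <- rm_ancova_4level(Y, fx$group, fx$covariate),
                 "dropped")
  expect_identical(attr(res, "n"), 11L)
})

test_that("univariate ANCOVA matches car's Type III analysis", {
  set.seed(14)
  for (i in 1:3) {
    n <- 18 + 2 * i
    group <- sample(rep(c("glucose", "sucralose"), length.out = n))
    covariate <- rnorm(n, 17, 5)
    y <- 0.4 * covariate + (group == "glucose") * 2 + rnorm(n)
    res <- univariate_ancova(y, group, covariate)
    ref <- univariate_oracle(y, group, covariate)
    expect_equal(res$ss[res$effect == "Drink"], ref$group$ss,
                 tolerance = 1e-8)
    expect_equal(res$ss[res$effect == "Covariate"], ref$cov$ss,
                 tolerance = 1e-8)
    expect_equal(res$ss[res$effect == "Drink:Covariate"], ref$group_cov$ss,
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "Drink"], ref$group$f, tolerance = 1e-8)
    expect_equal(res$partial_eta_sq[res$effect == "Drink"],
                 ref$group$ss / (ref$group$ss + ref$err), tolerance = 1e-8)
  }
})
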