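# Independent oracles used across the suite. Each re-derives a quantity from
# first principles (explicit sums, refits, step-up loops) so that agreement
# with the package is a genuine cross-check, not a tautology.

# Pearson r and two-sided p from explicit covariance sums.
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

# Benjamini-Hochberg step-up flags by direct enumeration of the largest k
# with p(k) <= k * delta / m.
bh_brute <- function(p, delta) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[o[i]] <= i * delta / m) k <- i
  flags <- logical(m)
  if (k > 0L) flags[o[seq_len(k)]] <- TRUE
  flags
}

# Trapezoid of the baseline-subtracted series, by an explicit segment loop.
auci_brute <- function(h, grid) {
  d <- h - h[1]
  area <- 0
  for (i in seq_len(length(h) - 1))
    area <- area + (grid[i + 1] - grid[i]) * (d[i] + d[i + 1]) / 2
  area
}

# Least-squares residuals from the normal equations (no lm()).
resid_normal_eq <- function(v, z) {
  X <- cbind(1, z)
  as.vector(v - X %*% solve(t(X) %*% X, t(X) %*% v))
}

partial_r_brute <- function(x, y, z) {
  rx <- resid_normal_eq(x, z)
  ry <- resid_normal_eq(y, z)
  n <- length(x)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  tval <- r * sqrt((n - 3) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 3))
}

# Cook's distance by leave-one-out refitting:
# D_i = sum_j (yhat_j - yhat_j^(-i))^2 / (p * MSE).
cooks_brute <- function(y, x) {
  n <- length(y)
  fit <- stats::lm(y ~ x)
  yhat <- stats::fitted(fit)
  mse <- sum(stats::resid(fit)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    f2 <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- cbind(1, x) %*% stats::coef(f2)
    sum((yhat - yhat_i)^2) / (2 * mse)
  }, numeric(1))
}

# Mixed-design ANCOVA oracle via car::Anova's Type III univariate
# repeated-measures table (multivariate lm route, centered covariate,
# effects-coded group) — an independent design-matrix least-squares path.
ancova_oracle <- function(Y, group, covariate) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  g <- factor(group)
  cc <- covariate - mean(covariate)
  mlm <- stats::lm(Y ~ g * cc,
                   contrasts = list(g = stats::contr.sum))
  idata <- data.frame(time = ordered(seq_len(p)))
  a <- car::Anova(mlm, idata = idata, idesign = ~time, type = 3)
  # only the univariate table is consumed; HF-epsilon warnings are irrelevant
  tab <- suppressWarnings(summary(a, multivariate = FALSE))$univariate.tests
  rn <- rownames(tab)
  pick <- function(name) {
    stopifnot(name %in% rn)
    list(ss = tab[name, "Sum Sq"], f = tab[name, "F value"],
         df1 = tab[name, "num Df"], df2 = tab[name, "den Df"],
         err = tab[name, "Error SS"], p = tab[name, "Pr(>F)"])
  }
  list(time = pick("time"),
       time_group = pick("g:time"),
       time_cov = pick("cc:time"),
       time_group_cov = pick("g:cc:time"),
       group = pick("g"),
       cov = pick("cc"),
       group_cov = pick("g:cc"))
}

univariate_oracle <- function(y, group, covariate) {
  g <- factor(group)
  cc <- covariate - mean(covariate)
  fit <- stats::lm(y ~ g * cc, contrasts = list(g = stats::contr.sum))
  a <- car::Anova(fit, type = 3)
  list(group = list(ss = a["g", "Sum Sq"], f = a["g", "F value"]),
       cov = list(ss = a["cc", "Sum Sq"], f = a["cc", "F value"]),
       group_cov = list(ss = a["g:cc", "Sum Sq"], f = a["g:cc", "F value"]),
       err = a["Residuals", "Sum Sq"])
}

# Small simulated cohort used as a deterministic fixture by several files.
fixture_cohort <- function(n = 10, seed = 404) {
  simulate_cohort(simulation_config(n = n, seed = seed))$cohort
}

# A random split-plot fixture with real (nonzero) effects for oracle checks.
random_ancova_fixture <- function(n, p, seed) {
  set.seed(seed)
  group <- rep(c("glucose", "sucralose"), length.out = n)
  covariate <- rnorm(n, 20, 5)
  subj <- rnorm(n, 50, 8)
  Y <- sapply(seq_len(p), function(j)
    subj + j * 2 + rnorm(n, 0, 4) +
      (group == "glucose") * j * rnorm(1, 1, 1) +
      0.2 * covariate * (j - (p + 1) / 2))
  list(Y = Y, group = group, covariate = covariate)
}
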