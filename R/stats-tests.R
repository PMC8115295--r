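#' Zero-order Pearson correlation with a two-sided test
#'
#' Pairwise-deletes incomplete pairs, then reports the product-moment
#' correlation with the two-sided p-value from the t transform on n - 2
#' degrees of freedom. Degenerate inputs (fewer than 3 complete pairs, or a
#' zero-variance series) yield an `NA` result with a warning rather than an
#' error, so single failed cells do not abort a whole correlation table.
#'
#' @param x,y Numeric vectors of equal length.
#' @param var1,var2 Optional labels carried into the result.
#' @return One-row data frame: `var1`, `var2`, `r`, `n`, `p`.
#' @export
pearson_test <- function(x, y, var1 = "x", var2 = "y") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  res <- data.frame(var1 = var1, var2 = var2, r = NA_real_, n = n,
                    p = NA_real_, stringsAsFactors = FALSE)
  if (n < 3L) {
    warning("pearson_test: fewer than 3 complete pairs for ", var1, " ~ ", var2)
    return(res)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("pearson_test: zero variance in ", var1, " ~ ", var2)
    return(res)
  }
  ct <- cor.test(x, y, method = "pearson")
  res$r <- unname(ct$estimate)
  res$p <- ct$p.value
  res
}

#' Partial correlation controlling for one covariate
#'
#' Correlation between the least-squares residuals of `x` and `y` after
#' regressing each on `covariate`; the p-value uses the t transform on n - 3
#' degrees of freedom. A zero-variance covariate falls back to the plain
#' Pearson correlation with a warning.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector partialled out of both.
#' @param var1,var2 Optional labels.
#' @return One-row data frame: `var1`, `var2`, `r`, `n`, `p`.
#' @export
partial_correlation <- function(x, y, covariate, var1 = "x", var2 = "y") {
  ok <- complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; z <- covariate[ok]
  n <- length(x)
  res <- data.frame(var1 = var1, var2 = var2, r = NA_real_, n = n,
                    p = NA_real_, stringsAsFactors = FALSE)
  if (n < 4L) {
    warning("partial_correlation: fewer than 4 complete triples")
    return(res)
  }
  if (sd(z) == 0) {
    warning("partial_correlation: zero-variance covariate; plain Pearson used")
    pc <- pearson_test(x, y, var1, var2)
    pc$n <- n
    return(pc)
  }
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    warning("partial_correlation: a variable is fully explained by the covariate")
    return(res)
  }
  r <- cor(rx, ry)
  df <- n - 3L
  res$r <- r
  if (abs(r) >= 1) {
    res$p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    res$p <- 2 * pt(-abs(tval), df)
  }
  res
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure over one family of p-values at level `delta`: with
#' ordered p-values p(1) <= ... <= p(m), all hypotheses up to the largest k
#' with p(k) <= k * delta / m are flagged. Adjusted p-values are the standard
#' monotone BH values, so `significant` is equivalent to `p_adjusted <= delta`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (no NAs; exclude
#'   undefined tests from the family before calling).
#' @param delta FDR level, default 0.05.
#' @return Data frame with `p`, `p_adjusted`, `significant`, in input order.
#' @export
bh_fdr <- function(pvalues, delta = 0.05) {
  if (length(pvalues) == 0L)
    return(data.frame(p = numeric(), p_adjusted = numeric(),
                      significant = logical()))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("bh_fdr() requires p-values in [0, 1] with no NAs")
  adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, significant = adj <= delta)
}

#' Independent-samples t test with Levene's homogeneity check
#'
#' Two-sided pooled-variance t test (Welch by request) for a two-arm
#' between-subjects comparison, reporting group means and standard errors,
#' the 95% confidence interval of the mean difference, and the p-value of
#' Levene's test (centered at the group means) for equality of variances.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 2).
#' @param labels Group labels, default `c("glucose", "sucralose")`.
#' @param var_equal Pooled-variance t when `TRUE` (default), Welch otherwise.
#' @return One-row data frame with group means/ses, `t`, `df`, `p`,
#'   `ci_low`, `ci_high`, `levene_p`.
#' @export
independent_t <- function(x, y, labels = c("glucose", "sucralose"),
                          var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("independent_t() needs at least 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) != mean(y))
    stop("independent_t(): zero within-group variance with different means; ",
         "t statistic is unbounded")
  tt <- t.test(x, y, var.equal = var_equal)
  g <- factor(rep(labels, c(length(x), length(y))), levels = labels)
  lev <- tryCatch(
    car::leveneTest(c(x, y) ~ g, center = "mean")[1, "Pr(>F)"],
    error = function(e) NA_real_)
  if (!is.na(lev) && is.nan(lev)) lev <- NA_real_
  out <- data.frame(
    mean_1 = mean(x), se_1 = sd(x) / sqrt(length(x)),
    mean_2 = mean(y), se_2 = sd(y) / sqrt(length(y)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    levene_p = lev)
  names(out)[1:4] <- c(paste0("mean_", labels[1]), paste0("se_", labels[1]),
                       paste0("mean_", labels[2]), paste0("se_", labels[2]))
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, matching the package's reporting of
#' condition-balance checks. A zero row or column marginal makes the expected
#' counts degenerate; the result is then `NA` with a warning.
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p`, `n`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("chi_square_2x2() needs a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("chi_square_2x2: zero marginal; statistic undefined")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                n = sum(tab)))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = sum(tab))
}

#' Median split of a trait score
#'
#' Dichotomises a continuous trait for follow-up probes: values at or below
#' the median are `LOW`, values above are `HIGH` (ties at the median go low).
#'
#' @param trait Numeric vector, n >= 2, not all identical.
#' @return Factor with levels `LOW`, `HIGH`.
#' @export
median_split <- function(trait) {
  x <- trait[!is.na(trait)]
  if (length(x) < 2L) stop("median_split() needs at least 2 values")
  if (length(unique(x)) == 1L)
    stop("median_split(): all values identical, split impossible")
  m <- median(x)
  factor(ifelse(trait <= m, "LOW", "HIGH"), levels = c("LOW", "HIGH"))
}

#' Cook's distance outlier policy for satiety-divergence scores
#'
#' Regresses the index on its trait predictor, computes Cook's distance for
#' every point, flags points above threshold (`"4overN"`: the conventional
#' 4/n rule; `"0.2"`: a fixed cutoff replicating the reported removal of cases
#' with D > 0.2), and replaces flagged index values with the mean of the
#' unflagged values. A degenerate regression (zero-variance predictor) flags
#' nothing, with a warning.
#'
#' @param y Index values (the variable cleaned).
#' @param x Predictor used in the influence regression.
#' @param mode Threshold mode, `"4overN"` (default) or `"0.2"`.
#' @param ids Optional identifiers aligned with `y` for reporting.
#' @return List with `y` (cleaned, original length), `replaced_ids`,
#'   `cooks_d` (NA where pairs were incomplete), `threshold`, `n`.
#' @export
cooks_outlier_policy <- function(y, x, mode = c("4overN", "0.2"), ids = NULL) {
  mode <- match.arg(mode)
  if (length(y) != length(x)) stop("y and x must be the same length")
  if (is.null(ids)) ids <- as.character(seq_along(y))
  ok <- complete.cases(y, x)
  n <- sum(ok)
  if (n < 5L) stop("cooks_outlier_policy() needs at least 5 complete pairs")
  cooks_full <- rep(NA_real_, length(y))
  threshold <- if (mode == "4overN") 4 / n else 0.2
  if (sd(x[ok]) == 0) {
    warning("cooks_outlier_policy: zero-variance predictor; nothing flagged")
    return(list(y = y, replaced_ids = character(), cooks_d = cooks_full,
                threshold = threshold, n = n))
  }
  fit <- lm(y[ok] ~ x[ok])
  rss <- sum(resid(fit)^2)
  tss <- sum((y[ok] - mean(y[ok]))^2)
  if (rss <= 1e-10 * max(tss, 1e-12)) {
    # (near-)perfect fit: residuals are round-off, no point is influential
    cooks_full[ok] <- 0
    return(list(y = y, replaced_ids = character(), cooks_d = cooks_full,
                threshold = threshold, n = n))
  }
  d <- cooks.distance(fit)
  d[!is.finite(d)] <- 0
  cooks_full[ok] <- d
  flagged <- ok & !is.na(cooks_full) & cooks_full > threshold
  y_clean <- y
  if (any(flagged)) {
    keep <- ok & !flagged
    if (!any(keep)) {
      warning("cooks_outlier_policy: every point flagged; nothing replaced")
      flagged[] <- FALSE
    } else {
      y_clean[flagged] <- mean(y[keep])
    }
  }
  list(y = y_clean, replaced_ids = ids[flagged], cooks_d = cooks_full,
       threshold = threshold, n = n)
}
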