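# Mixed-design (split-plot) ANCOVA with a two-level between factor and one
# continuous covariate, computed by the classical univariate decomposition:
# the repeated measurements are projected onto an orthonormal basis separating
# the subject mean (between-subjects stratum) from p - 1 within-subject
# contrasts; each stratum is analysed with a Type III least-squares model
# (effects-coded group, grand-mean-centered covariate), and within-subject
# sums of squares are pooled over the contrasts (sphericity assumed, no
# correction). For a 2-level within factor this reduces exactly to linear
# models on the difference score and the subject mean.

.rss <- function(X, y) {
  sum(qr.resid(qr(X), as.matrix(y))^2)
}

.effects_design <- function(group, covariate) {
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("the between-subjects factor must have exactly 2 levels")
  ge <- ifelse(g == levels(g)[1], 1, -1)
  cc <- covariate - mean(covariate)
  cbind(intercept = 1, g = ge, c = cc, gc = ge * cc)
}

.type3_drop_ss <- function(X, Y) {
  # Type III SS for each column of X by drop-in-residual-sum-of-squares,
  # summed over the columns of Y.
  rss_full <- .rss(X, Y)
  ss <- vapply(seq_len(ncol(X)), function(j)
    .rss(X[, -j, drop = FALSE], Y) - rss_full, numeric(1))
  list(ss = ss, rss = rss_full)
}

.ancova_rows <- function(effect, ss, df1, sse, dfe) {
  ss <- pmax(ss, 0) # guard tiny negative round-off
  f <- ifelse(ss == 0, 0, (ss / df1) / (sse / dfe))
  pes <- ifelse(ss == 0, 0, ss / (ss + sse))
  data.frame(effect = effect, ss = ss, df1 = df1, df2 = dfe, F = f,
             p = stats::pf(f, df1, dfe, lower.tail = FALSE),
             partial_eta_sq = pes,
             stringsAsFactors = FALSE)
}

# A stratum whose total sum of squares is round-off relative to the data
# carries no signal: zero out its effect and error SS so F = 0, not 0/0.
.null_stratum <- function(Z, Y) {
  sum(Z^2) <= 1e-12 * max(1, sum(Y^2))
}

.split_plot_ancova <- function(Y, group, covariate,
                               within_label, between_label, covariate_label) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  ok <- complete.cases(Y, group, covariate)
  if (any(!ok))
    warning(sum(!ok), " subject(s) dropped for incomplete measurements")
  Y <- Y[ok, , drop = FALSE]
  group <- group[ok]
  covariate <- covariate[ok]
  n <- nrow(Y)
  if (n < 5L) stop("mixed-design ANCOVA needs at least 5 complete subjects")
  if (length(unique(group)) != 2L)
    stop("both between-subject groups must be represented")
  X <- .effects_design(group, covariate)

  lab <- function(...) paste(c(...), collapse = ":")
  # Between-subjects stratum: orthonormal subject-mean direction.
  z0 <- Y %*% rep(1 / sqrt(p), p)
  btw <- .type3_drop_ss(X, z0)
  dfe_b <- n - 4L
  between <- .ancova_rows(
    c(between_label, covariate_label, lab(between_label, covariate_label)),
    btw$ss[2:4], 1L, btw$rss, dfe_b)

  # Within-subjects stratum: orthonormal polynomial contrasts, SS pooled
  # across contrasts (univariate approach, sphericity assumed).
  M <- contr.poly(p)
  Z <- Y %*% M
  wth <- .type3_drop_ss(X, Z)
  if (.null_stratum(Z, Y)) {
    wth$ss[] <- 0
    wth$rss <- 0
  }
  dfe_w <- (p - 1L) * (n - 4L)
  within <- .ancova_rows(
    c(within_label,
      lab(within_label, between_label),
      lab(within_label, covariate_label),
      lab(within_label, between_label, covariate_label)),
    wth$ss, p - 1L, wth$rss, dfe_w)

  out <- rbind(within, between)
  attr(out, "n") <- n
  attr(out, "error_ss") <- c(within = wth$rss, between = btw$rss)
  class(out) <- c("interosat_ancova", "data.frame")
  out
}

#' Mixed-design ANCOVA with a two-level repeated factor
#'
#' Two measurements per subject (e.g. a rating before and after tasting), a
#' two-level between-subjects drink factor, and one continuous covariate
#' centered at its grand mean. Within-subject effects (the repeated factor and
#' its interactions with drink and the covariate) come from a Type III linear
#' model on the orthonormalised difference score; between-subject effects from
#' the model on the subject mean. For a two-level repeated factor this is the
#' exact classical mixed-model ANCOVA. With n complete subjects every effect
#' is tested on (1, n - 4) degrees of freedom.
#'
#' @param y_before,y_after Numeric vectors: the two repeated measurements.
#' @param group Two-level between-subjects factor (drink condition).
#' @param covariate Continuous covariate.
#' @param within_label,between_label,covariate_label Labels used in the
#'   `effect` column.
#' @return Data frame of class `interosat_ancova` with columns `effect`,
#'   `ss`, `df1`, `df2`, `F`, `p`, `partial_eta_sq`.
#' @export
rm_ancova_2level <- function(y_before, y_after, group, covariate,
                             within_label = "Taste", between_label = "Drink",
                             covariate_label = "Covariate") {
  .split_plot_ancova(cbind(y_before, y_after), group, covariate,
                     within_label, between_label, covariate_label)
}

#' Mixed-design ANCOVA with a four-level repeated (time) factor
#'
#' Four measurements per subject on the 0/15/30/60-minute grid, a two-level
#' between-subjects drink factor, and one continuous covariate. Uses the
#' univariate split-plot sums of squares with sphericity assumed (no
#' correction), pooling Type III sums of squares over three orthonormal
#' polynomial time contrasts. With 62 complete subjects the within-subject
#' effects are tested on (3, 174) degrees of freedom.
#'
#' @param Y Numeric matrix or data frame, one row per subject, four columns
#'   in time order.
#' @param group Two-level between-subjects factor.
#' @param covariate Continuous covariate.
#' @param within_label,between_label,covariate_label Labels for the `effect`
#'   column.
#' @return Data frame of class `interosat_ancova` (see [rm_ancova_2level()]).
#' @export
rm_ancova_4level <- function(Y, group, covariate,
                             within_label = "Time", between_label = "Drink",
                             covariate_label = "Covariate") {
  if (ncol(as.matrix(Y)) != 4L)
    stop("rm_ancova_4level() expects 4 repeated measurements per subject")
  .split_plot_ancova(Y, group, covariate,
                     within_label, between_label, covariate_label)
}

#' Univariate ANCOVA (one observation per subject)
#'
#' Type III analysis of a single outcome on a two-level drink factor, a
#' continuous covariate (grand-mean centered) and their interaction, with
#' effects-coded group. Used for interoceptive coherence and the
#' sweetness/liking manipulation checks.
#'
#' @param y Outcome vector.
#' @param group Two-level between-subjects factor.
#' @param covariate Continuous covariate.
#' @param between_label,covariate_label Labels for the `effect` column.
#' @return Data frame of class `interosat_ancova` with one row per effect.
#' @export
univariate_ancova <- function(y, group, covariate,
                              between_label = "Drink",
                              covariate_label = "Covariate") {
  ok <- complete.cases(y, group, covariate)
  if (any(!ok)) warning(sum(!ok), " subject(s) dropped for missing values")
  y <- y[ok]; group <- group[ok]; covariate <- covariate[ok]
  n <- length(y)
  if (n < 5L) stop("univariate ANCOVA needs at least 5 complete subjects")
  X <- .effects_design(group, covariate)
  t3 <- .type3_drop_ss(X, y)
  out <- .ancova_rows(
    c(between_label, covariate_label,
      paste(between_label, covariate_label, sep = ":")),
    t3$ss[2:4], 1L, t3$rss, n - 4L)
  attr(out, "n") <- n
  attr(out, "error_ss") <- c(between = t3$rss)
  class(out) <- c("interosat_ancova", "data.frame")
  out
}
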