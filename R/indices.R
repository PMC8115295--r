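#' Anticipated satiety divergence
#'
#' Quantifies how closely a participant's post-prandial satiety matched their
#' anticipated satiety: `1 - |E - A| / (E + A)` for expected satiety `E` and
#' actual (experienced) satiety `A`, both VAS millimetres. The score lies in
#' `[0, 1]` whenever both inputs are in range and not both zero; 1 means the
#' expectation was met exactly (an expectation-driven participant), lower
#' values mean a larger divergence (a sensation-driven participant).
#'
#' When `E = A = 0` the ratio is 0/0; the result is `NA` with a warning so the
#' undefined case propagates as missing rather than biasing cohort
#' correlations.
#'
#' @param expected Expected-satiety VAS rating in `[0, 100]` mm.
#' @param actual Actual-satiety (fullness) VAS rating in `[0, 100]` mm.
#' @return Divergence score in `[0, 1]`, or `NA` for the 0/0 case.
#' @examples
#' satiety_divergence(80, 20) # 0.4
#' @export
satiety_divergence <- function(expected, actual) {
  if (is.na(expected) || is.na(actual)) return(NA_real_)
  if (expected < 0 || expected > 100 || actual < 0 || actual > 100)
    stop("satiety_divergence() inputs must be VAS values in [0, 100]")
  if (expected == 0 && actual == 0) {
    warning("satiety divergence undefined for expected = actual = 0; NA returned")
    return(NA_real_)
  }
  1 - abs(expected - actual) / (expected + actual)
}

#' Arcsine transform for proportion-like scores
#'
#' `asin(x)` for `x` in `[0, 1]`, in radians; monotone increasing onto
#' `[0, pi/2]`. Used to bring satiety-divergence scores closer to normality
#' before the parametric battery. Values within 1e-9 of the bounds are
#' clipped; anything further outside is an error.
#'
#' @param x Numeric vector in `[0, 1]` (NA passed through).
#' @return Transformed values in radians.
#' @export
arcsine_transform <- function(x) {
  eps <- 1e-9
  bad <- !is.na(x) & (x < -eps | x > 1 + eps)
  if (any(bad))
    stop("arcsine_transform() input outside [0, 1]: ",
         paste(signif(x[bad], 6), collapse = ", "))
  asin(pmin(1, pmax(0, x)))
}

#' Interoceptive coherence
#'
#' Within-person Pearson correlation between the blood-glucose and hunger
#' trajectories over the 0/15/30/60-minute grid, used as an index of how
#' strongly unfolding physiological signals drive the participant's reported
#' hunger. The `"signed"` (primary) variant reverses the sign so that +1 means
#' hunger fell exactly as glucose rose; the `"absolute"` (supplementary)
#' variant takes the absolute correlation, treating any strong linear
#' glucose-hunger coupling as coherence.
#'
#' @param glucose Four blood-glucose values (mmol/L) on the time grid.
#' @param hunger Four hunger VAS values (mm) on the same grid.
#' @param variant `"signed"` or `"absolute"`.
#' @return Correlation-based coherence; `NA` with a warning if either series
#'   has zero variance.
#' @examples
#' interoceptive_coherence(c(5, 6, 7, 8), c(80, 70, 60, 50)) # 1
#' @export
interoceptive_coherence <- function(glucose, hunger,
                                    variant = c("signed", "absolute")) {
  variant <- match.arg(variant)
  if (length(glucose) != 4L || length(hunger) != 4L)
    stop("interoceptive_coherence() needs 4 glucose and 4 hunger values")
  if (anyNA(glucose) || anyNA(hunger)) return(NA_real_)
  if (sd(glucose) == 0 || sd(hunger) == 0) {
    warning("interoceptive coherence undefined: zero variance in a series")
    return(NA_real_)
  }
  r <- cor(glucose, hunger)
  if (variant == "signed") -r else abs(r)
}

#' Incremental area under the hunger curve
#'
#' Baseline-anchored trapezoidal area of `H(t) - H(0)` over the session, in
#' mm x min. Negative values indicate hunger suppressed below its fasting
#' baseline across the hour; positive values indicate rebound hunger.
#'
#' @param hunger Hunger VAS values (mm) on `grid`.
#' @param grid Sampling times in minutes, default `c(0, 15, 30, 60)`.
#' @return Incremental area in mm*min (`NA` if any value is missing).
#' @examples
#' rebound_hunger_auci(c(60, 30, 40, 50)) # -1050
#' @export
rebound_hunger_auci <- function(hunger, grid = c(0, 15, 30, 60)) {
  if (length(hunger) != length(grid))
    stop("rebound_hunger_auci(): hunger series length ", length(hunger),
         " does not match the time grid length ", length(grid))
  if (anyNA(hunger)) return(NA_real_)
  pracma::trapz(grid, hunger - hunger[1])
}

#' Post-load change in blood glucose
#'
#' `G(60) - G(0)` in mmol/L. After a glucose load, a larger positive delta at
#' 60 minutes indicates a slower return to baseline, read in the paradigm as
#' poorer glucoregulation.
#'
#' @param glucose Four blood-glucose values (mmol/L) on the 0/15/30/60 grid.
#' @return Change in mmol/L (`NA` if an endpoint is missing).
#' @export
glucose_delta <- function(glucose) {
  if (length(glucose) != 4L)
    stop("glucose_delta() needs exactly 4 values, got ", length(glucose))
  glucose[4] - glucose[1]
}

#' Compute all interoceptive indices for one participant
#'
#' Derives the full per-participant index set from a cohort row: satiety
#' divergence before/after tasting (expected satiety vs the fullness rating
#' made ten minutes after consumption), their arcsine-transformed analysis
#' values when configured, signed and absolute interoceptive coherence, the
#' confidence and expected-satiety updates (after minus before tasting), the
#' baseline-anchored incremental hunger area, and the 60-minute glucose delta.
#' Undefined index values propagate as `NA`.
#'
#' @param record A one-row data frame (or list) with cohort fields.
#' @param config An [analysis_config()].
#' @return A one-row data frame of indices keyed by `id`.
#' @export
compute_indices <- function(record, config = analysis_config()) {
  g <- as.numeric(record[paste0("glucose_", config$time_grid)])
  h <- as.numeric(record[paste0("hunger_", config$time_grid)])
  sd_bt <- satiety_divergence(as.numeric(record[["exp_satiety_bt"]]),
                              as.numeric(record[["fullness_15"]]))
  sd_at <- satiety_divergence(as.numeric(record[["exp_satiety_at"]]),
                              as.numeric(record[["fullness_15"]]))
  ic <- interoceptive_coherence(g, h, "signed")
  out <- data.frame(
    id = as.character(record[["id"]]),
    condition = tolower(as.character(record[["condition"]])),
    dif = as.numeric(record[["dif_score"]]),
    bmi = as.numeric(record[["bmi"]]),
    esc_bt = as.numeric(record[["esc_bt"]]),
    esc_at = as.numeric(record[["esc_at"]]),
    sd_bt = sd_bt,
    sd_at = sd_at,
    ic = ic,
    ic_abs = if (is.na(ic)) NA_real_ else abs(ic),
    esc_update = as.numeric(record[["esc_at"]]) -
      as.numeric(record[["esc_bt"]]),
    exp_satiety_update = as.numeric(record[["exp_satiety_at"]]) -
      as.numeric(record[["exp_satiety_bt"]]),
    auci_hunger = rebound_hunger_auci(h, config$time_grid),
    glucose_delta_60 = glucose_delta(g),
    stringsAsFactors = FALSE)
  if (config$sd_transform == "arcsine") {
    out$sd_bt_x <- arcsine_transform(sd_bt)
    out$sd_at_x <- arcsine_transform(sd_at)
  }
  out
}

#' Compute the indices table for a whole cohort
#'
#' Applies [compute_indices()] row-wise and returns one indices row per
#' participant, keyed by id.
#'
#' @inheritParams compute_indices
#' @param cohort A cohort data frame.
#' @return A data frame with one row per participant.
#' @export
compute_indices_table <- function(cohort, config = analysis_config()) {
  rows <- lapply(seq_len(nrow(cohort)), function(i)
    compute_indices(as.data.frame(cohort)[i, , drop = FALSE], config))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
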