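#' Configuration of the precision-weighted Bayesian-observer cohort generator
#'
#' The generator treats each simulated participant as a Bayesian observer who
#' combines a prior satiety expectation with interoceptive (blood-glucose
#' linked) evidence, each weighted by its precision. The trait score (DIF,
#' difficulty identifying feelings, 7-35) maps log-linearly onto both
#' precisions: `log pi_prior = a0 - a1 * z(DIF)` and
#' `log pi_sens = b0 + b1 * z(DIF)`, so higher-DIF observers hold less precise
#' priors and weight sensory evidence more (sensory weight
#' `w = pi_sens / (pi_prior + pi_sens)`).
#'
#' @param n Participants per drink condition (the two-arm study used 31).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param dif_mean,dif_sd Trait distribution on the 7-35 scale (defaults match
#'   the arm means/SDs of roughly 16.7 and 5.6 reported for the paradigm).
#' @param prior_precision Coefficients `c(a0, a1)` of the prior-precision map.
#' @param sensory_precision Coefficients `c(b0, b1)` of the sensory map.
#' @param glucose_kinetics Baseline `g0_mean`/`g0_sd` (mmol/L), excursion
#'   amplitude `amp` (mmol/L), time to peak `tp` (minutes, in (0, 60)),
#'   `tail_frac` (fraction of the peak still present at 60 min),
#'   `tail_dif` (increase of the tail fraction per z(DIF), generating the
#'   poorer glucoregulation of high-DIF observers), and meter noise `meas_sd`.
#'   The sucralose arm stays flat at baseline.
#' @param hunger_model Baseline fasting hunger `h0_mean`/`h0_sd` (mm),
#'   physiological gain `k` (mm per mmol/L of glucose excursion), predicted
#'   post-drink suppression `s` (mm), and sucralose rebound drift `rho`
#'   (mm/min applied to the physiological signal after minute 15).
#' @param noise Observation noise: `vas_sd` (mm) for every VAS report.
#' @param confidence_map Logistic map from log prior precision to confidence
#'   VAS: `100 * plogis(c0 + c1 * log pi_prior)`; after tasting, observers
#'   whose prior precision exceeds `prior_threshold` gain `gain` on the logit
#'   scale (low-DIF observers become more confident after tasting, high-DIF
#'   do not).
#' @param expectation_model `e_update`: maximal mm shift of expected satiety
#'   after tasting, scaled by (1 - confidence), so confident observers barely
#'   update their expectation.
#' @param bmi_model Mean/SD of BMI, its positive coupling to z(DIF), and the
#'   height distribution used to back out weight.
#' @param hedonics Sweetness and liking VAS distributions; `liking_dif` is
#'   the mm change in liking per z(DIF) (negative: high-DIF observers like
#'   the drinks less).
#' @return A list of class `interosat_simulation_config`.
#' @seealso [simulate_cohort()], [null_simulation_config()]
#' @export
simulation_config <- function(
    n = 31,
    seed = 1,
    dif_mean = 16.7, dif_sd = 5.6,
    prior_precision = c(a0 = 0, a1 = 0.8),
    sensory_precision = c(b0 = 0, b1 = 0.8),
    glucose_kinetics = list(g0_mean = 4.9, g0_sd = 0.3, amp = 3, tp = 30,
                            tail_frac = 0.25, tail_dif = 0.15,
                            meas_sd = 0.15),
    hunger_model = list(h0_mean = 70, h0_sd = 8, k = 8, s = 30, rho = 0.4),
    noise = list(vas_sd = 5),
    confidence_map = list(c0 = 0.3, c1 = 1.2, gain = 1.2,
                          prior_threshold = 1),
    expectation_model = list(e_update = 8),
    bmi_model = list(mean = 24.3, sd = 3.5, dif_coupling = 1.5,
                     height_mean = 1.65, height_sd = 0.07),
    hedonics = list(sweet_mean = 49, sweet_sd = 18, liking_mean = 60,
                    liking_sd = 18, liking_dif = -5)) {
  cfg <- list(n = n, seed = seed, dif_mean = dif_mean, dif_sd = dif_sd,
              prior_precision = prior_precision,
              sensory_precision = sensory_precision,
              glucose_kinetics = glucose_kinetics,
              hunger_model = hunger_model, noise = noise,
              confidence_map = confidence_map,
              expectation_model = expectation_model,
              bmi_model = bmi_model, hedonics = hedonics)
  stopifnot(cfg$n >= 1, cfg$dif_sd >= 0,
            cfg$glucose_kinetics$tp > 0, cfg$glucose_kinetics$tp < 60,
            cfg$glucose_kinetics$g0_sd >= 0,
            cfg$glucose_kinetics$meas_sd >= 0,
            cfg$hunger_model$h0_sd >= 0, cfg$noise$vas_sd >= 0)
  class(cfg) <- "interosat_simulation_config"
  cfg
}

#' Null (trait-decoupled) simulation configuration
#'
#' Same generator, but every coupling between the trait score and the
#' generative process is switched off: precisions, the glucose tail, BMI and
#' liking are all independent of DIF. Under this configuration any
#' trait-index association is a false positive, which makes the configuration
#' the reference point for type-I-error experiments.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return An `interosat_simulation_config`.
#' @export
null_simulation_config <- function(...) {
  cfg <- simulation_config(...)
  cfg$prior_precision[["a1"]] <- 0
  cfg$sensory_precision[["b1"]] <- 0
  cfg$glucose_kinetics$tail_dif <- 0
  cfg$bmi_model$dif_coupling <- 0
  cfg$hedonics$liking_dif <- 0
  cfg
}

# Random composition of a DIF score into 7 items in 1..5 summing to it.
.dif_items_for_score <- function(score) {
  items <- integer(7)
  rem <- as.integer(score)
  for (i in 1:7) {
    m <- 7L - i
    lo <- max(1L, rem - 5L * m)
    hi <- min(5L, rem - m)
    items[i] <- if (lo >= hi) lo else sample(lo:hi, 1L)
    rem <- rem - items[i]
  }
  sample(items)
}

# Single-peak glucose excursion shape on [0, 60]: linear rise to 1 at tp,
# then linear decay towards the residual tail fraction at 60 min.
.glucose_shape <- function(t, tp, tail_frac) {
  ifelse(t <= tp, t / tp, 1 - (1 - tail_frac) * (t - tp) / (60 - tp))
}

#' Simulate a single participant
#'
#' Draws one participant from the precision-weighted observer model under the
#' given drink condition, using the current RNG state. The latent physiology
#' is a rise-and-fall glucose excursion (glucose arm) or a flat trajectory
#' (sucralose arm); physiological hunger falls with the glucose excursion and,
#' in the sucralose arm, drifts upward after minute 15 (rebound). Reported
#' hunger is the precision-weighted blend of the prior prediction (baseline
#' minus the expected suppression) and the physiological signal, plus VAS
#' noise, clipped to 0-100 mm. Expected satiety and fullness are
#' 100-complements of predicted/reported hunger; confidence follows the
#' logistic map of log prior precision.
#'
#' @param config An [simulation_config()].
#' @param condition `"glucose"` or `"sucralose"`.
#' @param dif Optional pre-drawn trait score (used by [simulate_cohort()] to
#'   match the arms); drawn from the trait distribution when `NULL`.
#' @param id Participant identifier.
#' @return List with `record` (one cohort row) and `truth` (one row of
#'   generating values: `pi_prior`, `pi_sens`, sensory weight `w`, latent
#'   baselines).
#' @export
simulate_participant <- function(config, condition = c("glucose", "sucralose"),
                                 dif = NULL, id = "P001") {
  condition <- match.arg(condition)
  gk <- config$glucose_kinetics
  hm <- config$hunger_model
  cm <- config$confidence_map
  vas_sd <- config$noise$vas_sd
  grid <- .time_grid

  if (is.null(dif))
    dif <- min(35L, max(7L, as.integer(round(
      rnorm(1, config$dif_mean, config$dif_sd)))))
  z <- (dif - config$dif_mean) / config$dif_sd
  log_pp <- config$prior_precision[["a0"]] - config$prior_precision[["a1"]] * z
  log_ps <- config$sensory_precision[["b0"]] +
    config$sensory_precision[["b1"]] * z
  pi_prior <- exp(log_pp)
  pi_sens <- exp(log_ps)
  w <- pi_sens / (pi_prior + pi_sens)

  g0 <- rnorm(1, gk$g0_mean, gk$g0_sd)
  if (condition == "glucose") {
    tail_i <- min(0.9, max(0.05, gk$tail_frac + gk$tail_dif * z))
    g_true <- g0 + gk$amp * .glucose_shape(grid, gk$tp, tail_i)
  } else {
    tail_i <- NA_real_
    g_true <- rep(g0, 4L)
  }
  g_obs <- pmax(0.1, g_true + rnorm(4, 0, gk$meas_sd))

  h0 <- rnorm(1, hm$h0_mean, hm$h0_sd)
  # Prior prediction: fasting hunger at baseline, suppressed by s thereafter.
  h_pred <- c(h0, rep(h0 - hm$s, 3L))
  h_phys <- h0 - hm$k * (g_true - g0)
  if (condition == "sucralose")
    h_phys <- h_phys + hm$rho * pmax(0, grid - 15)
  h_post <- (1 - w) * h_pred + w * h_phys
  hunger <- .clip_vas(h_post + rnorm(4, 0, vas_sd))

  conf_bt <- plogis(cm$c0 + cm$c1 * log_pp)
  gain_i <- if (pi_prior > cm$prior_threshold) cm$gain else 0
  conf_at <- plogis(cm$c0 + cm$c1 * (log_pp + gain_i))
  esc_bt <- .clip_vas(100 * conf_bt + rnorm(1, 0, vas_sd))
  esc_at <- .clip_vas(100 * conf_at + rnorm(1, 0, vas_sd))

  e_core <- 100 - (h0 - hm$s)
  exp_bt <- .clip_vas(e_core + rnorm(1, 0, vas_sd))
  exp_at <- .clip_vas(e_core + config$expectation_model$e_update *
                        (1 - conf_bt) + rnorm(1, 0, vas_sd))
  fullness <- .clip_vas(100 - h_post[2] + rnorm(1, 0, vas_sd))

  bm <- config$bmi_model
  height <- rnorm(1, bm$height_mean, bm$height_sd)
  bmi <- max(16, rnorm(1, bm$mean + bm$dif_coupling * z, bm$sd))
  weight <- bmi * height^2

  hd <- config$hedonics
  sweetness <- .clip_vas(rnorm(1, hd$sweet_mean, hd$sweet_sd))
  liking <- .clip_vas(rnorm(1, hd$liking_mean + hd$liking_dif * z,
                            hd$liking_sd))
  items <- .dif_items_for_score(dif)

  record <- data.frame(
    id = id, condition = condition,
    dif_1 = items[1], dif_2 = items[2], dif_3 = items[3], dif_4 = items[4],
    dif_5 = items[5], dif_6 = items[6], dif_7 = items[7],
    dif_score = dif,
    height_m = height, weight_kg = weight, bmi = bmi,
    exp_satiety_bt = exp_bt, exp_satiety_at = exp_at,
    esc_bt = esc_bt, esc_at = esc_at,
    fullness_15 = fullness,
    hunger_0 = hunger[1], hunger_15 = hunger[2], hunger_30 = hunger[3],
    hunger_60 = hunger[4],
    glucose_0 = g_obs[1], glucose_15 = g_obs[2], glucose_30 = g_obs[3],
    glucose_60 = g_obs[4],
    sweetness = sweetness, liking = liking,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    id = id, condition = condition, dif = dif, dif_z = z,
    pi_prior = pi_prior, pi_sens = pi_sens, w = w,
    h0 = h0, g0 = g0, tail_frac = tail_i,
    stringsAsFactors = FALSE)
  list(record = record, truth = truth)
}

#' Simulate a two-arm cohort matched on the trait score
#'
#' Draws `2 * n` trait scores, sorts them, and splits each consecutive pair at
#' random between the glucose and sucralose arms, so the arms are matched on
#' DIF by construction. The whole cohort is reproducible from `config$seed`.
#'
#' @param config An [simulation_config()].
#' @return List with `cohort` (validated `interosat_cohort`, one row per
#'   participant) and `truth` (data frame of generating values aligned by id).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n2 <- 2L * config$n
  dif <- pmin(35L, pmax(7L, as.integer(round(
    rnorm(n2, config$dif_mean, config$dif_sd)))))
  conditions <- character(n2)
  ord <- order(dif)
  for (k in seq_len(config$n)) {
    pair <- ord[c(2L * k - 1L, 2L * k)]
    first_glucose <- sample(c(TRUE, FALSE), 1L)
    conditions[pair] <- if (first_glucose) c("glucose", "sucralose") else
      c("sucralose", "glucose")
  }
  sims <- lapply(seq_len(n2), function(i)
    simulate_participant(config, conditions[i], dif = dif[i],
                         id = sprintf("P%03d", i)))
  cohort <- do.call(rbind, lapply(sims, `[[`, "record"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(cohort) <- rownames(truth) <- NULL
  cohort <- .as_cohort(cohort,
                       metadata = list(source = "simulated",
                                       seed = config$seed, n_per_arm = config$n))
  list(cohort = cohort, truth = truth)
}
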