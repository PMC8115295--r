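#' Run the full analysis pipeline on a cohort
#'
#' End-to-end battery: per-participant indices; Cook's-distance outlier
#' replacement on the satiety-divergence variables (regressed on the trait
#' score) followed by the configured arcsine transform; per-condition
#' zero-order correlations among confidence, divergence, coherence, trait and
#' BMI with Benjamini-Hochberg control per condition table; pooled partial
#' correlations of the trait with each index controlling BMI; independent t
#' tests across drinks; the three two-level mixed ANCOVAs (expected-satiety
#' updating with before-tasting confidence as covariate, divergence and
#' confidence with the trait as covariate); a univariate ANCOVA for
#' coherence, sweetness and liking; four-level mixed ANCOVAs for hunger and
#' glucose; and follow-up probes (within-condition correlations, and a
#' median-split comparison of 60-minute glucose) for interactions that pass
#' the FDR level. Analyses whose preconditions fail (e.g. too few
#' participants in an arm) are skipped with a recorded reason, never
#' silently.
#'
#' @param cohort A validated cohort (see [read_cohort()], [simulate_cohort()]).
#' @param config An [analysis_config()].
#' @return A list of class `interosat_report` with elements `indices`,
#'   `correlations`, `partial_correlations`, `group_comparisons`, `ancova`
#'   (named list of tables), `probes`, `outliers`, `skipped`, `provenance`.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  idx <- compute_indices_table(cohort, config)
  skipped <- list()
  skip <- function(name, reason)
    skipped[[name]] <<- reason
  try_table <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skip(name, conditionMessage(e))
      NULL
    })
  }

  # --- outlier policy on the SD variables, then the analysis transform ----
  outliers <- list()
  for (v in c("sd_bt", "sd_at")) {
    res <- try_table(paste0("outliers_", v),
                     cooks_outlier_policy(idx[[v]], idx$dif,
                                          mode = config$cooks_mode,
                                          ids = idx$id))
    if (!is.null(res)) {
      idx[[v]] <- res$y
      outliers[[v]] <- list(replaced_ids = res$replaced_ids,
                            threshold = res$threshold)
    }
  }
  if (config$sd_transform == "arcsine") {
    idx$sd_bt_x <- arcsine_transform(idx$sd_bt)
    idx$sd_at_x <- arcsine_transform(idx$sd_at)
    sd_bt_a <- idx$sd_bt_x
    sd_at_a <- idx$sd_at_x
  } else {
    sd_bt_a <- idx$sd_bt
    sd_at_a <- idx$sd_at
  }
  ic_a <- if (config$ic_variant == "absolute") idx$ic_abs else idx$ic

  adat <- data.frame(idx[c("id", "condition", "dif", "bmi", "esc_bt",
                           "esc_at", "esc_update", "exp_satiety_update",
                           "auci_hunger", "glucose_delta_60")],
                     sd_bt = sd_bt_a, sd_at = sd_at_a, ic = ic_a,
                     stringsAsFactors = FALSE)
  raw <- as.data.frame(cohort)
  drink <- factor(adat$condition, levels = c("glucose", "sucralose"))

  # --- per-condition zero-order correlation tables (Table-1 shape) --------
  corr_vars <- c("esc_bt", "esc_at", "sd_bt", "sd_at", "ic", "dif", "bmi")
  correlations <- NULL
  for (cond in levels(drink)) {
    sub <- adat[adat$condition == cond, ]
    if (nrow(sub) < 4L) {
      skip(paste0("correlations_", cond),
           "fewer than 4 participants in condition")
      next
    }
    pairs <- utils::combn(corr_vars, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j)
      suppressWarnings(pearson_test(sub[[pairs[1, j]]], sub[[pairs[2, j]]],
                                    pairs[1, j], pairs[2, j])))
    tab <- do.call(rbind, rows)
    tab <- cbind(condition = cond, tab)
    defined <- !is.na(tab$p)
    tab$p_adjusted <- NA_real_
    tab$significant <- NA
    if (any(defined)) {
      fdr <- bh_fdr(tab$p[defined], config$fdr_level)
      tab$p_adjusted[defined] <- fdr$p_adjusted
      tab$significant[defined] <- fdr$significant
    }
    correlations <- rbind(correlations, tab)
  }

  # --- pooled partial correlations of the trait controlling BMI ----------
  partial_vars <- c("esc_bt", "esc_at", "sd_bt", "sd_at", "ic",
                    "auci_hunger", "glucose_delta_60")
  partials <- try_table("partial_correlations", {
    rows <- lapply(partial_vars, function(v)
      suppressWarnings(partial_correlation(adat$dif, adat[[v]], adat$bmi,
                                           "dif", v)))
    tab <- do.call(rbind, rows)
    defined <- !is.na(tab$p)
    tab$p_adjusted <- NA_real_
    tab$significant <- NA
    if (any(defined)) {
      fdr <- bh_fdr(tab$p[defined], config$fdr_level)
      tab$p_adjusted[defined] <- fdr$p_adjusted
      tab$significant[defined] <- fdr$significant
    }
    tab
  })

  # --- independent t tests across drinks (Table-2 shape) ------------------
  t_vars <- c("esc_bt", "esc_at", "sd_bt", "sd_at", "ic", "auci_hunger")
  comparisons <- try_table("group_comparisons", {
    rows <- lapply(t_vars, function(v) {
      tt <- independent_t(adat[[v]][drink == "glucose"],
                          adat[[v]][drink == "sucralose"])
      cbind(variable = v, tt)
    })
    do.call(rbind, rows)
  })

  # --- ANCOVA battery ------------------------------------------------------
  ancova <- list()
  ancova$expected_satiety <- try_table("ancova_expected_satiety",
    rm_ancova_2level(raw$exp_satiety_bt, raw$exp_satiety_at, drink,
                     adat$esc_bt, covariate_label = "ESC-BT"))
  ancova$satiety_divergence <- try_table("ancova_satiety_divergence",
    rm_ancova_2level(adat$sd_bt, adat$sd_at, drink, adat$dif,
                     covariate_label = "DIF"))
  ancova$confidence <- try_table("ancova_confidence",
    rm_ancova_2level(adat$esc_bt, adat$esc_at, drink, adat$dif,
                     covariate_label = "DIF"))
  ancova$ic <- try_table("ancova_ic",
    univariate_ancova(adat$ic, drink, adat$dif, covariate_label = "DIF"))
  ancova$hunger <- try_table("ancova_hunger",
    rm_ancova_4level(as.matrix(raw[paste0("hunger_", config$time_grid)]),
                     drink, adat$dif, covariate_label = "DIF"))
  ancova$glucose <- try_table("ancova_glucose",
    rm_ancova_4level(as.matrix(raw[paste0("glucose_", config$time_grid)]),
                     drink, adat$dif, covariate_label = "DIF"))
  if (!is.null(raw$sweetness))
    ancova$sweetness <- try_table("ancova_sweetness",
      univariate_ancova(raw$sweetness, drink, adat$dif,
                        covariate_label = "DIF"))
  if (!is.null(raw$liking))
    ancova$liking <- try_table("ancova_liking",
      univariate_ancova(raw$liking, drink, adat$dif,
                        covariate_label = "DIF"))

  # --- follow-up probes of interactions that pass the FDR level ------------
  sig_of <- function(tab, effect) {
    !is.null(tab) && effect %in% tab$effect &&
      isTRUE(tab$p[tab$effect == effect] <= config$fdr_level)
  }
  probes <- NULL
  probe_cor <- function(label, x, y, cond = "pooled") {
    pc <- suppressWarnings(pearson_test(x, y))
    data.frame(probe = label, condition = cond, statistic = "r",
               estimate = pc$r, n = pc$n, p = pc$p, stringsAsFactors = FALSE)
  }
  if (sig_of(ancova$hunger, "Time:Drink:DIF")) {
    for (cond in levels(drink)) {
      sel <- drink == cond
      for (t in config$time_grid[-1]) {
        probes <- rbind(probes, probe_cor(
          sprintf("dif_vs_hunger_%d", t),
          adat$dif[sel], raw[[paste0("hunger_", t)]][sel], cond))
      }
    }
  }
  if (sig_of(ancova$glucose, "Time:Drink:DIF")) {
    probes <- rbind(probes,
      probe_cor("dif_vs_glucose_60", adat$dif[drink == "glucose"],
                raw$glucose_60[drink == "glucose"], "glucose"),
      probe_cor("dif_vs_glucose_60", adat$dif[drink == "sucralose"],
                raw$glucose_60[drink == "sucralose"], "sucralose"))
    split_probe <- try_table("probe_glucose_median_split", {
      sel <- drink == "glucose"
      grp <- median_split(adat$dif)[sel]
      tt <- independent_t(raw$glucose_60[sel][grp == "HIGH"],
                          raw$glucose_60[sel][grp == "LOW"],
                          labels = c("high_dif", "low_dif"))
      data.frame(probe = "glucose_60_high_vs_low_dif", condition = "glucose",
                 statistic = "t", estimate = tt$t, n = sum(sel), p = tt$p,
                 stringsAsFactors = FALSE)
    })
    probes <- rbind(probes, split_probe)
  }
  if (sig_of(ancova$satiety_divergence, "Drink:DIF") ||
      sig_of(ancova$satiety_divergence, "Taste:Drink:DIF")) {
    for (cond in levels(drink)) {
      sel <- drink == cond
      probes <- rbind(probes,
        probe_cor("dif_vs_sd_at", adat$dif[sel], adat$sd_at[sel], cond),
        probe_cor("dif_vs_sd_bt", adat$dif[sel], adat$sd_bt[sel], cond))
    }
  }
  if (sig_of(ancova$confidence, "Taste:DIF")) {
    probes <- rbind(probes,
      probe_cor("dif_vs_esc_bt", adat$dif, adat$esc_bt),
      probe_cor("dif_vs_esc_at", adat$dif, adat$esc_at),
      probe_cor("dif_vs_esc_update", adat$dif, adat$esc_update))
  }
  if (sig_of(ancova$expected_satiety, "Taste:ESC-BT")) {
    probes <- rbind(probes,
      probe_cor("esc_bt_vs_exp_satiety_update", adat$esc_bt,
                adat$exp_satiety_update))
  }

  meta <- attr(cohort, "metadata")
  report <- list(
    indices = idx,
    analysis_values = adat,
    correlations = correlations,
    partial_correlations = partials,
    group_comparisons = comparisons,
    ancova = ancova,
    probes = probes,
    outliers = outliers,
    skipped = skipped,
    provenance = list(
      package = "interosat",
      version = as.character(packageVersion("interosat")),
      n = nrow(idx),
      fdr_level = config$fdr_level,
      ic_variant = config$ic_variant,
      sd_transform = config$sd_transform,
      cooks_mode = config$cooks_mode,
      seed = if (!is.null(config$rng_seed)) config$rng_seed else
        if (!is.null(meta$seed)) meta$seed else NA))
  class(report) <- "interosat_report"
  report
}

#' @export
print.interosat_report <- function(x, ...) {
  cat("interosat analysis report:", x$provenance$n, "participants\n")
  cat("  FDR level", x$provenance$fdr_level, "| IC variant",
      x$provenance$ic_variant, "| SD transform",
      x$provenance$sd_transform, "\n")
  ns <- if (is.null(x$correlations)) 0 else sum(x$correlations$significant,
                                                na.rm = TRUE)
  cat("  zero-order correlations flagged:", ns, "\n")
  for (nm in names(x$ancova)) {
    tab <- x$ancova[[nm]]
    if (is.null(tab)) next
    top <- tab[which.min(tab$p), ]
    cat(sprintf("  ANCOVA %-18s strongest effect %s: F(%d, %d) = %.3f, p = %.4g\n",
                nm, top$effect, top$df1, top$df2, top$F, top$p))
  }
  if (length(x$skipped) > 0)
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' One CSV per table (indices, correlations, partial correlations, group
#' comparisons, each ANCOVA, probes) plus a JSON manifest carrying the
#' configuration, outlier replacements and skipped analyses. The output
#' contains no timestamps, so identical inputs produce byte-identical
#' report directories.
#'
#' @param report An `interosat_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    path <- file.path(dir, paste0(name, ".csv"))
    write.csv(as.data.frame(tab), path, row.names = FALSE, na = "",
              fileEncoding = "UTF-8")
    files <<- c(files, basename(path))
  }
  emit(report$indices, "indices")
  emit(report$correlations, "correlations")
  emit(report$partial_correlations, "partial_correlations")
  emit(report$group_comparisons, "group_comparisons")
  for (nm in names(report$ancova))
    emit(report$ancova[[nm]], paste0("ancova_", nm))
  emit(report$probes, "probes")
  manifest <- list(provenance = report$provenance,
                   outliers = report$outliers,
                   skipped = report$skipped,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
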