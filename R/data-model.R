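#' Canonical cohort table columns
#'
#' One row per participant. VAS ratings are millimetres on a 0-100 visual
#' analogue scale; glucose is mmol/L; hunger and glucose are sampled at
#' 0, 15, 30 and 60 minutes. `dif_1`..`dif_7` are the seven
#' difficulty-identifying-feelings questionnaire items (1-5 each); `dif_score`
#' is their sum (7-35). Either the items or the score may be supplied, and
#' either `bmi` or both `height_m` and `weight_kg`.
#'
#' @return Character vector of canonical column names.
#' @export
cohort_columns <- function() {
  c("id", "condition",
    paste0("dif_", 1:7), "dif_score",
    "height_m", "weight_kg", "bmi",
    "exp_satiety_bt", "exp_satiety_at", "esc_bt", "esc_at",
    "fullness_15",
    paste0("hunger_", .time_grid),
    paste0("glucose_", .time_grid),
    "sweetness", "liking")
}

.vas_columns <- function() {
  c("exp_satiety_bt", "exp_satiety_at", "esc_bt", "esc_at", "fullness_15",
    paste0("hunger_", .time_grid), "sweetness", "liking")
}

#' Score the 7-item difficulty-identifying-feelings questionnaire
#'
#' Items are rated on a five-point scale (1 = strongly disagree, 5 = strongly
#' agree); the scale score is their sum, so it ranges 7-35 with higher values
#' indicating more difficulty identifying feelings.
#'
#' @param items Integer vector of exactly 7 item responses, each in 1..5.
#' @return Integer scale score in `[7, 35]`.
#' @examples
#' score_dif(c(1, 2, 3, 4, 5, 1, 2))
#' @export
score_dif <- function(items) {
  if (length(items) != 7L)
    stop("score_dif() needs exactly 7 items, got ", length(items))
  if (anyNA(items) || !is.numeric(items) || any(items != round(items)) ||
      any(items < 1 | items > 5))
    stop("DIF items must be integers in 1..5")
  as.integer(sum(items))
}

#' Body mass index
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(58.32, 1.8)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (!is.numeric(weight_kg) || !is.numeric(height_m) ||
      anyNA(weight_kg) || anyNA(height_m) ||
      any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight_kg and height_m must be strictly positive")
  weight_kg / height_m^2
}

#' Analysis configuration
#'
#' Options steering the statistical pipeline.
#'
#' @param fdr_level False-discovery-rate level delta for Benjamini-Hochberg
#'   control; the paradigm's analyses use 0.05.
#' @param ic_variant Which interoceptive-coherence variant enters the
#'   analyses: `"signed"` (reversed Pearson correlation, the primary variant)
#'   or `"absolute"` (absolute correlation, the supplementary variant).
#' @param sd_transform Transform applied to satiety-divergence scores before
#'   analysis: `"arcsine"` (asin of the raw score, the analysis scale used for
#'   group summaries) or `"none"`.
#' @param cooks_mode Threshold rule for Cook's-distance outlier replacement on
#'   the satiety-divergence variables: `"4overN"` (conventional 4/n) or
#'   `"0.2"` (fixed cutoff replicating the reported D > 0.2 removals).
#' @param time_grid Minutes at which hunger and glucose are sampled.
#' @param rng_seed Optional integer seed recorded in report provenance.
#' @return A list of class `interosat_analysis_config`.
#' @export
analysis_config <- function(fdr_level = 0.05,
                            ic_variant = c("signed", "absolute"),
                            sd_transform = c("arcsine", "none"),
                            cooks_mode = c("4overN", "0.2"),
                            time_grid = c(0, 15, 30, 60),
                            rng_seed = NULL) {
  if (!is.numeric(fdr_level) || length(fdr_level) != 1L ||
      fdr_level <= 0 || fdr_level >= 1)
    stop("fdr_level must be a probability strictly between 0 and 1")
  cfg <- list(fdr_level = fdr_level,
              ic_variant = match.arg(ic_variant),
              sd_transform = match.arg(sd_transform),
              cooks_mode = match.arg(cooks_mode),
              time_grid = time_grid,
              rng_seed = rng_seed)
  class(cfg) <- "interosat_analysis_config"
  cfg
}

#' Validate a cohort table
#'
#' Checks every row of a cohort table against the paradigm's invariants:
#' VAS ratings within 0-100 mm, strictly positive glucose, DIF items in 1..5
#' with `dif_score` equal to their sum, `dif_score` in 7..35, and `bmi`
#' consistent with `weight_kg / height_m^2` when both anthropometrics are
#' present. Missing optional values are permitted and propagate as `NA`.
#'
#' @param cohort A data frame with (a subset of) [cohort_columns()].
#' @return A data frame of problems with columns `row`, `field`, `message`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  problems <- list()
  note <- function(row, field, message) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, field = field, message = message,
      stringsAsFactors = FALSE)
  }

  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    note(NA_integer_, "(table)", "cohort must be a non-empty data frame")
    return(do.call(rbind, problems))
  }
  for (col in c("id", "condition")) {
    if (is.null(cohort[[col]])) {
      note(NA_integer_, col, "required column missing")
      return(do.call(rbind, problems))
    }
  }
  dup <- duplicated(cohort$id)
  for (i in which(dup)) note(i, "id", "duplicate participant id")

  cond <- tolower(as.character(cohort$condition))
  for (i in which(!cond %in% c("glucose", "sucralose")))
    note(i, "condition", "condition must be 'glucose' or 'sucralose'")

  num <- function(col) {
    x <- cohort[[col]]
    if (is.null(x)) return(rep(NA_real_, nrow(cohort)))
    suppressWarnings(as.numeric(x))
  }
  for (col in .vas_columns()) {
    x <- num(col)
    raw <- cohort[[col]]
    if (!is.null(raw)) {
      bad_num <- which(!is.na(raw) & raw != "" & is.na(x))
      for (i in bad_num) note(i, col, "non-numeric VAS value")
    }
    for (i in which(!is.na(x) & (x < 0 | x > 100)))
      note(i, col, sprintf("VAS value %g outside [0, 100] mm", x[i]))
  }
  for (col in paste0("glucose_", .time_grid)) {
    x <- num(col)
    for (i in which(!is.na(x) & x <= 0))
      note(i, col, sprintf("blood glucose %g mmol/L is not positive", x[i]))
  }

  item_cols <- paste0("dif_", 1:7)
  has_items <- all(item_cols %in% names(cohort))
  if (has_items) {
    items <- as.matrix(cohort[item_cols])
    for (i in seq_len(nrow(cohort))) {
      row_items <- items[i, ]
      if (anyNA(row_items)) next
      if (any(row_items != round(row_items) | row_items < 1 | row_items > 5)) {
        note(i, "dif_items", "DIF items must be integers in 1..5")
      } else if (!is.null(cohort$dif_score) && !is.na(cohort$dif_score[i]) &&
                 cohort$dif_score[i] != sum(row_items)) {
        note(i, "dif_score", "dif_score does not equal the sum of dif_1..dif_7")
      }
    }
  }
  ds <- num("dif_score")
  for (i in which(!is.na(ds) & (ds < 7 | ds > 35 | ds != round(ds))))
    note(i, "dif_score", "dif_score must be an integer in 7..35")

  h <- num("height_m"); w <- num("weight_kg"); b <- num("bmi")
  for (i in which(!is.na(h) & h <= 0)) note(i, "height_m", "height must be > 0")
  for (i in which(!is.na(w) & w <= 0)) note(i, "weight_kg", "weight must be > 0")
  both <- !is.na(h) & h > 0 & !is.na(w) & w > 0 & !is.na(b)
  for (i in which(both & abs(b - w / h^2) > 1e-9))
    note(i, "bmi", "bmi inconsistent with weight_kg / height_m^2")

  if (length(problems) == 0L)
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

.derive_fields <- function(cohort) {
  item_cols <- paste0("dif_", 1:7)
  if (all(item_cols %in% names(cohort))) {
    items <- as.matrix(cohort[item_cols])
    sums <- rowSums(items)
    if (is.null(cohort$dif_score)) cohort$dif_score <- NA_real_
    fill <- is.na(cohort$dif_score) & !is.na(sums)
    cohort$dif_score[fill] <- sums[fill]
  }
  if (!is.null(cohort$height_m) && !is.null(cohort$weight_kg)) {
    ok <- !is.na(cohort$height_m) & !is.na(cohort$weight_kg) &
      cohort$height_m > 0 & cohort$weight_kg > 0
    if (is.null(cohort$bmi)) cohort$bmi <- NA_real_
    fill <- is.na(cohort$bmi) & ok
    cohort$bmi[fill] <- cohort$weight_kg[fill] / cohort$height_m[fill]^2
  }
  cohort$condition <- tolower(as.character(cohort$condition))
  cohort
}

.as_cohort <- function(df, metadata = list()) {
  df <- .derive_fields(df)
  problems <- validate_cohort(df)
  if (nrow(problems) > 0L) {
    msgs <- sprintf("row %s, field %s: %s",
                    ifelse(is.na(problems$row), "-", problems$row),
                    problems$field, problems$message)
    stop("invalid cohort table:\n  ",
         paste(utils::head(msgs, 20L), collapse = "\n  "),
         if (nrow(problems) > 20L) "\n  ..." else "",
         call. = FALSE)
  }
  attr(df, "metadata") <- metadata
  class(df) <- c("interosat_cohort", "data.frame")
  df
}

#' Read a cohort table from a delimited text file
#'
#' Reads a comma-separated, UTF-8, header-carrying cohort file (one row per
#' participant, columns per [cohort_columns()]), optionally renaming columns
#' through `schema`, derives `dif_score` and `bmi` where only their raw
#' ingredients are present, and validates every row. Validation failures abort
#' with row- and field-level diagnostics.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(dif_score = "TAS_DIF", bmi = "BodyMassIndex")`.
#' @return A validated cohort data frame of class `interosat_cohort`.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df))
        stop("schema column '", src, "' (for '", canonical,
             "') not present in ", path)
      names(df)[names(df) == src] <- canonical
    }
  }
  missing <- setdiff(c("id", "condition"), names(df))
  if (length(missing) > 0L)
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "))
  .as_cohort(df, metadata = list(source = path))
}

#' Write a cohort table to CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces every field exactly.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  keep <- intersect(cohort_columns(), names(out))
  out <- out[c(keep, setdiff(names(out), keep))]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      x <- out[[col]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      out[[col]] <- s
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
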