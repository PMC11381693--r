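#' Grip-strength classification configuration
#'
#' Sarcopenia risk is operationalised as maximum grip strength below a
#' sex-specific cut-point. Two presets are packaged: `"grip_2sd"`, cut-points
#' two standard deviations below young-adult reference means (<32 kg for men,
#' <19 kg for women), and `"ewgsop2"`, the EWGSOP2 probable-sarcopenia
#' thresholds (<27 kg men, <16 kg women) used as a sensitivity analysis.
#' Participants unable to perform the test for health reasons are classified
#' as at risk when `unable_counts_as_at_risk` is `TRUE` (the default).
#'
#' @param preset `"grip_2sd"` or `"ewgsop2"`; ignored when both thresholds are
#'   given explicitly.
#' @param male_threshold_kg,female_threshold_kg Explicit cut-points (kg).
#' @param unable_counts_as_at_risk Classify the "unable for health reasons"
#'   group as at risk.
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(preset = c("grip_2sd", "ewgsop2"),
                                  male_threshold_kg = NULL,
                                  female_threshold_kg = NULL,
                                  unable_counts_as_at_risk = TRUE) {
  if (is.null(male_threshold_kg) != is.null(female_threshold_kg)) {
    stop("give both thresholds or neither")
  }
  if (is.null(male_threshold_kg)) {
    preset <- match.arg(preset)
    thr <- switch(preset,
                  grip_2sd = c(male = 32, female = 19),
                  ewgsop2  = c(male = 27, female = 16))
    male_threshold_kg <- thr[["male"]]
    female_threshold_kg <- thr[["female"]]
  } else {
    preset <- "custom"
  }
  if (male_threshold_kg <= 0 || female_threshold_kg <= 0) {
    stop("thresholds must be strictly positive")
  }
  structure(list(preset = preset,
                 male_threshold_kg = male_threshold_kg,
                 female_threshold_kg = female_threshold_kg,
                 unable_counts_as_at_risk = isTRUE(unable_counts_as_at_risk)),
            class = "classification_config")
}

cohort_base_cols <- c("participant_id", "sex", "age_years", "grip_max_kg",
                      "unable_health")

#' Condition indicator columns of a cohort table
#' @noRd
condition_cols <- function(cohort, registry) {
  ids <- registry$condition_id
  missing <- setdiff(ids, names(cohort))
  if (length(missing)) {
    stop("cohort is missing condition columns: ", paste(missing, collapse = ", "))
  }
  ids
}

#' Validate a cohort table against a registry
#'
#' Checks the column contract of the participant-level table: base columns,
#' one 0/1 indicator per registry condition, sex codes, and structural zeros
#' for sex-restricted conditions. Recomputes `n_ltc`.
#'
#' @param cohort A data frame in the cohort dialect (see [read_cohort_csv()]).
#' @param registry An `ltc_registry`.
#' @return The validated cohort with `n_ltc` recomputed.
#' @export
validate_cohort <- function(cohort, registry) {
  miss <- setdiff(cohort_base_cols, names(cohort))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  bad_sex <- setdiff(unique(cohort$sex), c("female", "male"))
  if (length(bad_sex)) {
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         " (expected \"female\"/\"male\")")
  }
  ids <- condition_cols(cohort, registry)
  for (id in ids) {
    v <- cohort[[id]]
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("condition column not 0/1: ", id)
    }
  }
  restricted <- registry[!is.na(registry$sex_restricted), , drop = FALSE]
  if (nrow(restricted)) {
    for (i in seq_len(nrow(restricted))) {
      id <- restricted$condition_id[i]
      other <- cohort$sex != restricted$sex_restricted[i]
      if (any(cohort[[id]][other] != 0L)) {
        stop("sex-restricted condition '", id, "' positive for excluded sex")
      }
    }
  }
  cohort$n_ltc <- as.integer(rowSums(cohort[ids]))
  cohort
}

#' Classify sarcopenia risk from maximum grip strength
#'
#' Applies the sex-specific cut-points with strict inequality: a participant
#' is at risk iff `grip_max_kg` is strictly below the threshold for their sex,
#' or they were unable to perform the test for health reasons (when the
#' configuration counts that group as at risk). Missing grip with
#' `unable_health = FALSE` leaves `at_risk` missing (unclassifiable).
#'
#' @param cohort Cohort table with `sex`, `grip_max_kg`, `unable_health`.
#' @param cfg A [classification_config()].
#' @return The cohort with a logical `at_risk` column added/replaced.
#' @examples
#' cfg <- classification_config()
#' df <- data.frame(participant_id = 1:3, sex = c("male", "female", "male"),
#'                  age_years = 60, grip_max_kg = c(31.9, 19.0, NA),
#'                  unable_health = c(FALSE, FALSE, TRUE))
#' classify_sarcopenia_risk(df, cfg)$at_risk  # TRUE FALSE TRUE
#' @export
classify_sarcopenia_risk <- function(cohort, cfg = classification_config()) {
  stopifnot(inherits(cfg, "classification_config"))
  bad_sex <- setdiff(unique(cohort$sex), c("female", "male"))
  if (length(bad_sex)) stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  thr <- ifelse(cohort$sex == "male", cfg$male_threshold_kg, cfg$female_threshold_kg)
  at_risk <- cohort$grip_max_kg < thr
  if (cfg$unable_counts_as_at_risk) {
    at_risk[cohort$unable_health] <- TRUE
  }
  # grip missing and not in the unable group: risk cannot be classified
  at_risk[is.na(cohort$grip_max_kg) & !cohort$unable_health] <- NA
  cohort$at_risk <- at_risk
  cohort
}

#' Restrict a cohort to classifiable participants with multimorbidity
#'
#' Keeps participants with at least `min_ltc` long-term conditions and a
#' non-missing `at_risk` classification; row order is preserved. This defines
#' the analytic sample: people living with multimorbidity whose sarcopenia
#' risk could be classified.
#'
#' @param cohort Classified cohort (see [classify_sarcopenia_risk()]); must
#'   have `n_ltc` (use [validate_cohort()] to derive it).
#' @param min_ltc Minimum number of conditions (default 2, i.e. MLTC).
#' @return The restricted cohort.
#' @export
restrict_to_mltc <- function(cohort, min_ltc = 2L) {
  if (is.null(cohort$at_risk)) stop("classify the cohort before restricting")
  if (is.null(cohort$n_ltc)) stop("cohort has no n_ltc column; run validate_cohort()")
  keep <- cohort$n_ltc >= min_ltc & !is.na(cohort$at_risk)
  out <- cohort[keep, , drop = FALSE]
  if (!nrow(out)) warning("restriction left an empty cohort")
  rownames(out) <- NULL
  out
}

#' Read / write a cohort CSV
#'
#' The cohort dialect is a header CSV with columns `participant_id, sex,
#' age_years, grip_max_kg, unable_health`, then one 0/1 column per registry
#' condition. `sex` is coded `F`/`M` on disk and `"female"`/`"male"` in
#' memory; missing grip is an empty field; `unable_health` is 0/1.
#'
#' @param path File path.
#' @param registry Registry the file must match.
#' @return `read_cohort_csv()`: a validated cohort data frame.
#' @export
read_cohort_csv <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sex <- c(F = "female", M = "male")[df$sex]
  df$unable_health <- df$unable_health == 1
  df$grip_max_kg <- as.numeric(df$grip_max_kg)
  validate_cohort(df, registry)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort to write.
#' @export
write_cohort_csv <- function(cohort, path, registry) {
  ids <- condition_cols(cohort, registry)
  out <- cohort[c(cohort_base_cols, ids)]
  out$sex <- c(female = "F", male = "M")[out$sex]
  out$unable_health <- as.integer(out$unable_health)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
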