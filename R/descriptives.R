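#' Sex-stratified descriptive statistics for an analytic cohort
#'
#' Summarises the restricted, classified cohort the way multimorbidity
#' baseline tables are usually presented: per sex, the sample size, median and
#' IQR of age, mean and SD of grip strength, the at-risk count and percentage,
#' the distribution of the number of long-term conditions, and per-condition
#' prevalences. Between-sex differences are tested with a two-sided
#' Mann-Whitney U test for age and Pearson chi-squared tests for all binary
#' variables.
#'
#' @param cohort Restricted, classified cohort.
#' @param registry The condition registry.
#' @param yates Apply Yates continuity correction in the chi-squared tests
#'   (default `FALSE`; the intended use is large samples).
#' @return A list of class `cohort_descriptives` with elements `by_sex` (a
#'   named list of per-sex summaries), `p_values` (named numeric vector:
#'   `age`, `at_risk`, `n_ltc`, and one per condition; `NA` where a test is
#'   undefined, e.g. a condition absent in both sexes).
#' @export
describe_cohort <- function(cohort, registry, yates = FALSE) {
  ids <- condition_cols(cohort, registry)
  sexes <- intersect(c("female", "male"), unique(cohort$sex))
  by_sex <- lapply(sexes, function(s) {
    d <- cohort[cohort$sex == s, , drop = FALSE]
    grip <- d$grip_max_kg[!is.na(d$grip_max_kg)]
    prev <- colMeans(d[ids])
    list(
      n = nrow(d),
      age_median = stats::median(d$age_years),
      age_iqr = unname(stats::quantile(d$age_years, c(0.25, 0.75))),
      grip_mean = mean(grip),
      grip_sd = stats::sd(grip),
      at_risk_n = sum(d$at_risk),
      at_risk_pct = 100 * mean(d$at_risk),
      n_ltc_table = table(factor(pmin(d$n_ltc, 6L), levels = 2:6,
                                 labels = c("2", "3", "4", "5", "6+"))),
      prevalence = prev,
      condition_n = colSums(d[ids])
    )
  })
  names(by_sex) <- sexes

  p_values <- c(age = NA_real_, at_risk = NA_real_, n_ltc = NA_real_)
  if (length(sexes) == 2L) {
    f <- cohort[cohort$sex == "female", ]
    m <- cohort[cohort$sex == "male", ]
    p_values["age"] <- stats::wilcox.test(f$age_years, m$age_years,
                                          exact = FALSE)$p.value
    p_values["at_risk"] <- chisq_p(table(cohort$sex, cohort$at_risk), yates)
    p_values["n_ltc"] <- chisq_p(table(cohort$sex, pmin(cohort$n_ltc, 6L)), yates)
    cond_p <- vapply(ids, function(id) {
      if (sum(cohort[[id]]) == 0L) return(NA_real_)
      reg_row <- registry[registry$condition_id == id, ]
      if (!is.na(reg_row$sex_restricted)) return(NA_real_)  # one-sex condition
      chisq_p(table(cohort$sex, cohort[[id]]), yates)
    }, numeric(1))
    p_values <- c(p_values, cond_p)
  } else {
    p_values <- c(p_values, stats::setNames(rep(NA_real_, length(ids)), ids))
  }
  structure(list(by_sex = by_sex, p_values = p_values),
            class = "cohort_descriptives")
}

chisq_p <- function(tab, yates = FALSE) {
  if (any(dim(tab) < 2L)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  for (s in names(x$by_sex)) {
    d <- x$by_sex[[s]]
    cat(sprintf("%s: n=%d, age %s (IQR %s-%s), grip %.2f (SD %.2f), at risk %d (%.2f%%)\n",
                s, d$n, format(d$age_median), format(d$age_iqr[1]),
                format(d$age_iqr[2]), d$grip_mean, d$grip_sd,
                d$at_risk_n, d$at_risk_pct))
  }
  invisible(x)
}

#' Write descriptives as per-sex CSV files plus a JSON summary
#' @param desc A `cohort_descriptives` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_descriptives <- function(desc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(desc$by_sex)) {
    d <- desc$by_sex[[s]]
    df <- data.frame(condition_id = names(d$prevalence),
                     n = as.integer(d$condition_n),
                     prevalence_pct = round(100 * unname(d$prevalence), 2))
    p <- file.path(dir, paste0("descriptives_", s, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "descriptives.json")
  jsonlite::write_json(
    list(by_sex = lapply(desc$by_sex, function(d) {
      d$n_ltc_table <- as.list(d$n_ltc_table)
      d
    }), p_values = as.list(desc$p_values)),
    jp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, jp))
}
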