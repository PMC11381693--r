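#' Logistic regression of sarcopenia risk on condition indicators
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], deviance convergence tolerance 1e-8) of the at-risk label
#' on one or more condition terms, optionally their product, and optionally
#' age as a continuous covariate. Complete or quasi-complete separation is
#' detected (fitted probabilities within 1e-8 of 0/1 together with a
#' diverging coefficient) and flagged rather than silently reported.
#'
#' @param cohort Restricted, classified cohort (single sex for the standard
#'   analysis).
#' @param terms Character vector of condition ids; `interaction = TRUE` adds
#'   the product of the first two.
#' @param interaction Include the pairwise product term.
#' @param adjust_age Add `age_years` as a covariate.
#' @return A list of class `logistic_fit`: `coefficients`, `covariance`,
#'   `or` (odds ratios with Wald 95% CIs), `n`, `converged`,
#'   `separation_flag`, and the underlying `glm` object.
#' @export
fit_logistic <- function(cohort, terms, interaction = FALSE,
                         adjust_age = FALSE) {
  miss <- setdiff(terms, names(cohort))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
  if (anyNA(cohort$at_risk)) stop("cohort contains unclassified participants")
  rhs <- terms
  if (interaction) {
    if (length(terms) < 2L) stop("interaction needs two terms")
    rhs <- c(rhs, paste0(terms[1], ":", terms[2]))
  }
  if (adjust_age) rhs <- c(rhs, "age_years")
  fml <- stats::as.formula(paste("at_risk ~", paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = cohort,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop("logistic fit did not converge within 100 IRLS iterations")
  }
  mu <- stats::fitted(fit)
  separation <- (any(mu < 1e-8) || any(mu > 1 - 1e-8)) &&
    any(abs(stats::coef(fit)) > 10)
  V <- stats::vcov(fit)
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  keep <- setdiff(names(est), "(Intercept)")
  or_tab <- data.frame(term = keep, or = exp(est[keep]),
                       ci_low = exp(est[keep] - z * se[keep]),
                       ci_high = exp(est[keep] + z * se[keep]),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = est, covariance = V, or = or_tab,
                 n = length(mu), converged = fit$converged,
                 separation_flag = separation, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d%s\n", x$n,
              if (x$separation_flag) " [separation flagged]" else ""))
  print(transform(x$or, or = round(or, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)))
  invisible(x)
}

#' Joint-exposure odds ratios for a condition pair
#'
#' Fits `logit P(at risk) = b0 + b1 A + b2 B + b3 A.B (+ b4 age)` and reports
#' the three exposure-cell odds ratios against the doubly-unexposed cell:
#' `or10 = exp(b1)` (A only), `or01 = exp(b2)` (B only),
#' `or11 = exp(b1 + b2 + b3)` (both), with Wald CIs (for `or11` from the
#' variance of the coefficient sum).
#'
#' @param cohort Restricted, classified cohort.
#' @param a,b Condition ids (distinct).
#' @param adjust_age Include age as a covariate.
#' @return A list of class `joint_ors`: `or10`, `or01`, `or11` (each a list
#'   `or`, `ci_low`, `ci_high`), plus the `logistic_fit`.
#' @export
joint_exposure_ors <- function(cohort, a, b, adjust_age = FALSE) {
  if (a == b) stop("conditions a and b must differ")
  cells <- table(factor(cohort[[a]], levels = 0:1),
                 factor(cohort[[b]], levels = 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty exposure cell (%s=%s, %s=%s)", a,
                 rownames(cells)[empty[1]], b, colnames(cells)[empty[2]]))
  }
  fit <- fit_logistic(cohort, c(a, b), interaction = TRUE,
                      adjust_age = adjust_age)
  cf <- fit$coefficients
  V <- fit$covariance
  nm <- c(a, b, paste0(a, ":", b))
  if (!all(nm %in% names(cf))) stop("interaction term missing from fit")
  z <- stats::qnorm(0.975)
  one_or <- function(l) {  # l: contrast vector over nm
    est <- sum(l * cf[nm])
    se <- sqrt(drop(t(l) %*% V[nm, nm] %*% l))
    list(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se))
  }
  structure(list(or10 = one_or(c(1, 0, 0)),
                 or01 = one_or(c(0, 1, 0)),
                 or11 = one_or(c(1, 1, 1)),
                 a = a, b = b, fit = fit),
            class = "joint_ors")
}

#' Relative excess risk due to interaction (RERI)
#'
#' Additive-scale interaction of two exposures from their joint-exposure odds
#' ratios: `RERI = OR11 - OR10 - OR01 + 1`. Zero means exact additivity of
#' risk differences (treating ORs as risk-ratio approximations); positive
#' values indicate a super-additive (synergistic) joint effect. The default
#' confidence interval is the delta method on
#' `(exp(b1), exp(b2), exp(b1+b2+b3))` using the fit covariance; a
#' nonparametric bootstrap (resampling participants) is available when the
#' underlying data are supplied.
#'
#' @param x A `joint_ors` object (for delta or bootstrap CIs), or a numeric
#'   vector/list of the three odds ratios `(or10, or01, or11)` (point
#'   estimate only, e.g. when re-evaluating published odds ratios).
#' @param method `"delta"` or `"bootstrap"`.
#' @param cohort,adjust_age Required for `method = "bootstrap"`: the data to
#'   resample and the model to refit.
#' @param n_boot Bootstrap replicates (percentile interval).
#' @param seed Seed for the bootstrap.
#' @return A list of class `reri_estimate`: `reri`, `ci` (`NULL` when only
#'   point estimates are available), `method`, `or10`, `or01`, `or11`.
#' @examples
#' reri(c(or10 = 1.11, or01 = 1.31, or11 = 4.74))$reri  # 3.32
#' @export
reri <- function(x, method = c("delta", "bootstrap"), cohort = NULL,
                 adjust_age = FALSE, n_boot = 2000L, seed = NULL) {
  method <- match.arg(method)
  if (is.numeric(x) || (is.list(x) && !inherits(x, "joint_ors"))) {
    v <- unlist(x)
    if (length(v) != 3L) stop("need exactly three odds ratios (or10, or01, or11)")
    est <- unname(v[3] - v[1] - v[2] + 1)
    return(structure(list(reri = est, ci = NULL, method = "point",
                          or10 = unname(v[1]), or01 = unname(v[2]),
                          or11 = unname(v[3])),
                     class = "reri_estimate"))
  }
  stopifnot(inherits(x, "joint_ors"))
  or10 <- x$or10$or; or01 <- x$or01$or; or11 <- x$or11$or
  est <- or11 - or10 - or01 + 1
  if (method == "delta") {
    cf <- x$fit$coefficients
    V <- x$fit$covariance
    nm <- c(x$a, x$b, paste0(x$a, ":", x$b))
    b1 <- cf[[nm[1]]]; b2 <- cf[[nm[2]]]; b3 <- cf[[nm[3]]]
    # gradient of exp(b1+b2+b3) - exp(b1) - exp(b2) + 1 wrt (b1, b2, b3)
    e11 <- exp(b1 + b2 + b3)
    g <- c(e11 - exp(b1), e11 - exp(b2), e11)
    se <- sqrt(drop(t(g) %*% V[nm, nm] %*% g))
    z <- stats::qnorm(0.975)
    ci <- c(est - z * se, est + z * se)
  } else {
    if (is.null(cohort)) stop("bootstrap CI needs the cohort to resample")
    if (is.null(seed)) stop("bootstrap CI needs a seed")
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(n_boot), function(i) {
      d <- cohort[sample.int(nrow(cohort), nrow(cohort), replace = TRUE), ]
      jo <- tryCatch(joint_exposure_ors(d, x$a, x$b, adjust_age = adjust_age),
                     error = function(e) NULL)
      if (is.null(jo)) return(NA_real_)
      jo$or11$or - jo$or10$or - jo$or01$or + 1
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(reri = est, ci = ci, method = method,
                 or10 = or10, or01 = or01, or11 = or11),
            class = "reri_estimate")
}

#' @export
print.reri_estimate <- function(x, ...) {
  cat(sprintf("RERI = %.2f", x$reri))
  if (!is.null(x$ci)) cat(sprintf(" (95%% CI %.2f to %.2f, %s)",
                                  x$ci[1], x$ci[2], x$method))
  cat(sprintf("  [OR10 %.2f, OR01 %.2f, OR11 %.2f]\n", x$or10, x$or01, x$or11))
  invisible(x)
}

#' Within-stratum odds ratios for a condition pair
#'
#' The association of each condition estimated separately in the presence and
#' absence of the other (effect modification), each from a logistic fit
#' restricted to the stratum. Together with the joint-exposure odds ratios
#' and the RERI this forms the standard presentation table for additive
#' interaction (Knol-VanderWeele layout).
#'
#' @inheritParams joint_exposure_ors
#' @return A data frame: `exposure`, `stratum`, `or`, `ci_low`, `ci_high`,
#'   `note` (reason when an OR is inestimable).
#' @export
stratified_ors <- function(cohort, a, b, adjust_age = FALSE) {
  if (a == b) stop("conditions a and b must differ")
  one <- function(exposure, stratum_var, stratum_val) {
    d <- cohort[cohort[[stratum_var]] == stratum_val, , drop = FALSE]
    lab <- sprintf("%s = %d", stratum_var, stratum_val)
    if (!nrow(d) || length(unique(d[[exposure]])) < 2L ||
        length(unique(d$at_risk)) < 2L) {
      return(data.frame(exposure = exposure, stratum = lab, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        note = "no variation in exposure or outcome within stratum",
                        stringsAsFactors = FALSE))
    }
    f <- fit_logistic(d, exposure, adjust_age = adjust_age)
    row <- f$or[f$or$term == exposure, ]
    data.frame(exposure = exposure, stratum = lab, or = row$or,
               ci_low = row$ci_low, ci_high = row$ci_high,
               note = if (f$separation_flag) "separation flagged" else "",
               stringsAsFactors = FALSE)
  }
  rbind(one(a, b, 1L), one(a, b, 0L), one(b, a, 1L), one(b, a, 0L))
}

#' Triangulate ranked combinations with logistic regression
#'
#' For each retained combination: per-condition odds ratios from single-term
#' fits; for two-condition combinations additionally the joint-exposure odds
#' ratios, the RERI with its CI, and the within-stratum odds ratios; for
#' combinations of three or more conditions, the per-condition odds ratios
#' and the odds ratio of the all-present exposure indicator (no RERI, which
#' is defined here for pairs only). A RERI is flagged significant when its
#' 95% CI excludes 0. No multiple-testing adjustment is applied; the number
#' of tests performed is reported.
#'
#' @param cohort Restricted, classified single-sex cohort.
#' @param ranked Output of [rank_and_retain()] (rows with `retained = TRUE`
#'   are analysed).
#' @param adjust_age Include age in every model.
#' @param ci_method `"delta"` or `"bootstrap"` for RERI intervals.
#' @param seed Needed for bootstrap intervals.
#' @return A list of class `triangulation`: `per_combination` (list, one
#'   element per combination with `conditions`, `label`, `condition_ors`,
#'   and for pairs `joint`, `reri`, `strata`; for larger sets
#'   `joint_exposure_or`), `n_tests`, `errors`.
#' @export
triangulate <- function(cohort, ranked, adjust_age = FALSE,
                        ci_method = c("delta", "bootstrap"), seed = NULL) {
  ci_method <- match.arg(ci_method)
  rows <- ranked[ranked$retained, , drop = FALSE]
  n_tests <- 0L
  errors <- character(0)
  per <- lapply(seq_len(nrow(rows)), function(i) {
    cc <- rows$conditions[[i]]
    rec <- list(conditions = cc, label = rows$label[i], rank = rows$rank[i])
    rec$condition_ors <- tryCatch({
      tab <- do.call(rbind, lapply(cc, function(id) {
        f <- fit_logistic(cohort, id, adjust_age = adjust_age)
        n_tests <<- n_tests + 1L
        f$or[f$or$term == id, ]
      }))
      rownames(tab) <- NULL
      tab
    }, error = function(e) {
      errors <<- c(errors, paste0(rows$label[i], ": ", conditionMessage(e)))
      NULL
    })
    if (length(cc) == 2L) {
      res <- tryCatch({
        jo <- joint_exposure_ors(cohort, cc[1], cc[2], adjust_age = adjust_age)
        rr <- reri(jo, method = ci_method, cohort = cohort,
                   adjust_age = adjust_age, seed = seed)
        st <- stratified_ors(cohort, cc[1], cc[2], adjust_age = adjust_age)
        n_tests <<- n_tests + 1L
        list(joint = jo, reri = rr, strata = st,
             reri_significant = !is.null(rr$ci) &&
               (rr$ci[1] > 0 || rr$ci[2] < 0))
      }, error = function(e) {
        errors <<- c(errors, paste0(rows$label[i], ": ", conditionMessage(e)))
        NULL
      })
      rec <- c(rec, res)
    } else if (length(cc) >= 3L) {
      rec$joint_exposure_or <- tryCatch({
        ind <- as.integer(rowSums(as.data.frame(cohort[cc])) == length(cc))
        d <- cohort
        d$.all_present <- ind
        f <- fit_logistic(d, ".all_present", adjust_age = adjust_age)
        n_tests <<- n_tests + 1L
        f$or[f$or$term == ".all_present", ]
      }, error = function(e) {
        errors <<- c(errors, paste0(rows$label[i], ": ", conditionMessage(e)))
        NULL
      })
    }
    rec
  })
  structure(list(per_combination = per, n_tests = n_tests, errors = errors,
                 adjust_age = adjust_age, ci_method = ci_method),
            class = "triangulation")
}

#' Flatten a triangulation report to a CSV-ready table
#'
#' One row per combination and term (per-condition ORs, joint-exposure cells,
#' RERI).
#'
#' @param tri A `triangulation`.
#' @param path Optional CSV path.
#' @export
triangulation_table <- function(tri, path = NULL) {
  rows <- list()
  for (rec in tri$per_combination) {
    lab <- rec$label
    if (!is.null(rec$condition_ors)) {
      for (j in seq_len(nrow(rec$condition_ors))) {
        r <- rec$condition_ors[j, ]
        rows[[length(rows) + 1L]] <- data.frame(
          combination = lab, term = r$term, quantity = "condition_or",
          estimate = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(rec$reri)) {
      jo <- rec$joint
      for (cell in c("or10", "or01", "or11")) {
        rows[[length(rows) + 1L]] <- data.frame(
          combination = lab, term = cell, quantity = "joint_or",
          estimate = jo[[cell]]$or, ci_low = jo[[cell]]$ci_low,
          ci_high = jo[[cell]]$ci_high, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combination = lab, term = "reri", quantity = "reri",
        estimate = rec$reri$reri, ci_low = rec$reri$ci[1],
        ci_high = rec$reri$ci[2], stringsAsFactors = FALSE)
    }
    if (!is.null(rec$joint_exposure_or)) {
      r <- rec$joint_exposure_or
      rows[[length(rows) + 1L]] <- data.frame(
        combination = lab, term = "all_present", quantity = "joint_or",
        estimate = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
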