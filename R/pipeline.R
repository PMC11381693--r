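#' Run the full combination-mining analysis on a cohort
#'
#' End-to-end, sex-stratified pipeline: classify sarcopenia risk from grip
#' strength, restrict to classifiable participants with multimorbidity, and
#' then per sex: descriptive statistics, a bagged cost-sensitive tree
#' ensemble, rule extraction and composite scoring, ranking with top-k
#' retention, confusion-matrix evaluation of each retained combination, and
#' (optionally) logistic-regression triangulation with RERI.
#'
#' A master seed is mandatory; per-stage child seeds are spawned from it by a
#' fixed scheme (one stream per sex) so results are reproducible and
#' per-stage work is order-independent.
#'
#' @param cohort_raw Unrestricted cohort (validated against `registry`).
#' @param registry An `ltc_registry`.
#' @param cls A [classification_config()].
#' @param hp A [tree_hyperparams()].
#' @param n_trees Ensemble size.
#' @param k Combinations to retain per sex.
#' @param seed Master seed.
#' @param fn_multiplier,freeze_loss Passed to [bootstrap_ensemble()].
#' @param do_triangulate Run the logistic triangulation stage.
#' @param adjust_age Age-adjust the triangulation models.
#' @param min_ltc Multimorbidity threshold.
#' @param exclude_features Condition ids removed from the tree feature set
#'   and combination space. Participants keep these conditions for the
#'   multimorbidity count, so eligibility is unchanged (used by the
#'   condition-removal sensitivity analysis).
#' @return A list of class `ltc_run` with `by_sex` (per-sex list:
#'   `descriptives`, `ensemble_summary`, `ranked`, `table`, `triangulation`),
#'   `config` (every setting in effect, including the full-sample loss
#'   matrices), and `n_analysed`.
#' @export
run_pipeline <- function(cohort_raw, registry, cls = classification_config(),
                         hp = tree_hyperparams(), n_trees = 1000L, k = 12L,
                         seed, fn_multiplier = 1, freeze_loss = FALSE,
                         do_triangulate = TRUE, adjust_age = FALSE,
                         min_ltc = 2L, exclude_features = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  cohort_raw <- validate_cohort(cohort_raw, registry)
  classified <- classify_sarcopenia_risk(cohort_raw, cls)
  analytic <- restrict_to_mltc(classified, min_ltc)
  desc <- describe_cohort(analytic, registry)
  sexes <- intersect(c("female", "male"), unique(analytic$sex))
  if (length(sexes) < 2L) {
    warning("cohort contains only one sex (", paste(sexes, collapse = ""),
            "); producing outputs for it alone")
  }
  set.seed(as.integer(seed))
  sex_seeds <- stats::setNames(sample.int(.Machine$integer.max, 2L),
                               c("female", "male"))
  by_sex <- lapply(sexes, function(s) {
    d <- analytic[analytic$sex == s, , drop = FALSE]
    reg_s <- registry_for_sex(registry, s)
    if (!is.null(exclude_features)) {
      for (id in exclude_features) reg_s <- registry_drop(reg_s, id)
    }
    ens <- bootstrap_ensemble(d, reg_s, hp, n_trees = n_trees,
                              seed = sex_seeds[[s]],
                              fn_multiplier = fn_multiplier,
                              freeze_loss = freeze_loss)
    recs <- composite_scores(ens)
    ranked <- rank_and_retain(recs, k)
    tab <- combination_table(ranked, d)
    tri <- if (do_triangulate && any(ranked$retained)) {
      triangulate(d, ranked, adjust_age = adjust_age, seed = sex_seeds[[s]])
    }
    list(sex = s, n = nrow(d), p_at_risk = mean(d$at_risk),
         loss = ens$meta$full_loss,
         ensemble_summary = ensemble_summary(recs),
         ranked = ranked, table = tab, triangulation = tri)
  })
  names(by_sex) <- sexes
  structure(list(by_sex = by_sex, descriptives = desc,
                 n_analysed = nrow(analytic),
                 config = list(classification = cls, hyperparams = hp,
                               n_trees = n_trees, k = k,
                               seed = as.integer(seed),
                               fn_multiplier = fn_multiplier,
                               freeze_loss = freeze_loss,
                               adjust_age = adjust_age, min_ltc = min_ltc,
                               exclude_features = exclude_features)),
            class = "ltc_run")
}

#' @export
print.ltc_run <- function(x, ...) {
  cat(sprintf("<ltc_run> %d participants analysed, %d trees/sex, top-%d\n",
              x$n_analysed, x$config$n_trees, x$config$k))
  for (s in names(x$by_sex)) {
    b <- x$by_sex[[s]]
    cat(sprintf("  %s: n=%d, at risk %.2f%%, fn penalty %.3f, %d combinations (%d in >=half)\n",
                s, b$n, 100 * b$p_at_risk, b$loss$fn_penalty,
                b$ensemble_summary$n_combinations, b$ensemble_summary$n_in_half))
  }
  invisible(x)
}

#' Write the outputs of a pipeline run to a directory
#'
#' Per sex: the ranked combination table (`combinations_<sex>.csv`), the
#' triangulation table (`triangulation_<sex>.csv`) and an ensemble summary;
#' plus cohort descriptives and a JSON run summary that round-trips every
#' numeric at full precision.
#'
#' @param run An `ltc_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_descriptives(run$descriptives, dir)
  summary <- list(n_analysed = run$n_analysed, config = list(
    classification = unclass(run$config$classification),
    hyperparams = unclass(run$config$hyperparams),
    n_trees = run$config$n_trees, k = run$config$k, seed = run$config$seed,
    fn_multiplier = run$config$fn_multiplier,
    freeze_loss = run$config$freeze_loss, min_ltc = run$config$min_ltc))
  for (s in names(run$by_sex)) {
    b <- run$by_sex[[s]]
    p1 <- file.path(dir, paste0("combinations_", s, ".csv"))
    utils::write.csv(b$table, p1, row.names = FALSE)
    paths <- c(paths, p1)
    if (!is.null(b$triangulation)) {
      p2 <- file.path(dir, paste0("triangulation_", s, ".csv"))
      triangulation_table(b$triangulation, p2)
      paths <- c(paths, p2)
    }
    summary[[paste0("ensemble_", s)]] <- c(
      b$ensemble_summary,
      list(p_at_risk = b$p_at_risk, fn_penalty = b$loss$fn_penalty))
  }
  pj <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' Simulate a cohort and write it in the cohort CSV dialect
#'
#' Convenience wrapper pairing [generate_cohort()] with [write_cohort_csv()]
#' and a ground-truth JSON sidecar.
#'
#' @param cfg A `simulation_config` (or preset name for [sim_preset()]).
#' @param dir Output directory.
#' @param seed Seed (mandatory).
#' @param registry Registry used to order/validate columns (defaults to a
#'   registry view matching the config's condition list).
#' @return Invisibly, a list with the cohort, ground truth and paths.
#' @export
pipeline_simulate <- function(cfg, dir, seed, registry = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(cfg)) cfg <- sim_preset(cfg)
  if (is.null(registry)) {
    full <- load_registry()
    keep <- full$condition_id %in% cfg$prevalence$condition_id
    registry <- as_registry(full[keep, , drop = FALSE])
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(cfg, seed)
  cohort_path <- file.path(dir, "cohort.csv")
  write_cohort_csv(sim$cohort, cohort_path, registry)
  gt <- sim$ground_truth
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = gt$seed,
         planted_pairs = gt$planted_pairs,
         grip_model = lapply(gt$grip_model, as.list)),
    gt_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = sim$cohort, ground_truth = gt,
                 paths = c(cohort_path, gt_path)))
}
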