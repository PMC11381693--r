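#' Rerun the pipeline under a sensitivity perturbation
#'
#' Four variants, one perturbation each:
#' * `"ewgsop2_thresholds"` — reclassify with the EWGSOP2 grip cut-points
#'   (<27 kg men, <16 kg women) and rerun everything from the raw cohort
#'   (thresholds change who is classifiable and at risk before restriction).
#' * `"doubled_fn_penalty"` — multiply the false-negative penalty by
#'   `penalty_multiplier` (default 2) wherever the loss matrix is computed.
#' * `"drop_condition"` — remove one condition (default hypertension, the
#'   most prevalent) from the feature set and combination space. Participants
#'   and their multimorbidity eligibility are unchanged: the removal probes
#'   whether the condition dominates the trees, not the sample definition.
#' * `"age_adjusted_logistic"` — keep the main ensemble results and refit the
#'   triangulation models with age as a continuous covariate.
#'
#' By default a variant reuses the main run's seed so top-k differences
#' reflect the perturbation rather than bootstrap noise; pass `fresh_seed`
#' to draw an independent stream.
#'
#' @param cohort_raw Raw (unrestricted) cohort.
#' @param registry The registry of the main analysis.
#' @param variant One of the four variant names.
#' @param main_config The `config` element of the main `ltc_run` (supplies
#'   classification preset, hyperparameters, ensemble size, k and seed).
#' @param penalty_multiplier For `"doubled_fn_penalty"`.
#' @param drop For `"drop_condition"`: the condition id to remove.
#' @param fresh_seed Optional replacement seed.
#' @return An `ltc_run` for the variant, with `$variant` recording the name.
#' @export
run_variant <- function(cohort_raw, registry, variant, main_config,
                        penalty_multiplier = 2, drop = "hypertension",
                        fresh_seed = NULL) {
  variant <- match.arg(variant, c("ewgsop2_thresholds", "doubled_fn_penalty",
                                  "drop_condition", "age_adjusted_logistic"))
  seed <- if (is.null(fresh_seed)) main_config$seed else as.integer(fresh_seed)
  args <- list(cohort_raw = cohort_raw, registry = registry,
               cls = main_config$classification,
               hp = main_config$hyperparams,
               n_trees = main_config$n_trees, k = main_config$k, seed = seed,
               fn_multiplier = main_config$fn_multiplier,
               freeze_loss = main_config$freeze_loss,
               adjust_age = main_config$adjust_age,
               min_ltc = main_config$min_ltc,
               exclude_features = main_config$exclude_features)
  if (variant == "ewgsop2_thresholds") {
    args$cls <- classification_config("ewgsop2")
  } else if (variant == "doubled_fn_penalty") {
    args$fn_multiplier <- main_config$fn_multiplier * penalty_multiplier
  } else if (variant == "drop_condition") {
    if (!drop %in% registry$condition_id) {
      stop("condition to drop is not in the registry: ", drop)
    }
    # feature removal only: n_ltc (and hence eligibility) keeps the condition
    args$exclude_features <- union(main_config$exclude_features, drop)
  } else if (variant == "age_adjusted_logistic") {
    args$adjust_age <- TRUE
  }
  run <- do.call(run_pipeline, args)
  run$variant <- variant
  run
}

#' Overlap of a variant's top-k combinations with the main analysis
#'
#' Combinations are compared as condition sets, ignoring rank.
#'
#' @param main_ranked,variant_ranked Outputs of [rank_and_retain()] for the
#'   same sex (only `retained` rows are compared).
#' @return A list of class `overlap_report`: `overlap` (count), `shared`,
#'   `main_only`, `variant_only` (character vectors of set keys).
#' @export
topk_overlap <- function(main_ranked, variant_ranked) {
  key <- function(r) vapply(r$conditions[r$retained], paste, character(1),
                            collapse = "+")
  km <- key(main_ranked); kv <- key(variant_ranked)
  structure(list(overlap = length(intersect(km, kv)),
                 k = attr(main_ranked, "k"),
                 shared = sort(intersect(km, kv)),
                 main_only = sort(setdiff(km, kv)),
                 variant_only = sort(setdiff(kv, km))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("top-%d overlap: %d shared\n", x$k, x$overlap))
  invisible(x)
}

#' Run a set of sensitivity variants and summarise top-k overlap
#'
#' @param cohort_raw Raw cohort used by the main run.
#' @param registry Registry of the main run.
#' @param main_run The main `ltc_run`.
#' @param variants Character vector of variant names (default: all four).
#' @param ... Passed to [run_variant()].
#' @return A list of class `sensitivity_suite`: `runs` (named list of
#'   variant `ltc_run`s) and `overlap` (data frame: variant, sex, overlap).
#' @export
run_sensitivity <- function(cohort_raw, registry, main_run,
                            variants = c("ewgsop2_thresholds",
                                         "doubled_fn_penalty",
                                         "drop_condition",
                                         "age_adjusted_logistic"), ...) {
  if (!inherits(main_run, "ltc_run")) stop("run the main analysis first")
  if (!length(variants)) {
    message("no variants requested; nothing to do")
    return(invisible(NULL))
  }
  runs <- lapply(variants, function(v) {
    run_variant(cohort_raw, registry, v, main_run$config, ...)
  })
  names(runs) <- variants
  rows <- list()
  for (v in variants) {
    for (s in intersect(names(main_run$by_sex), names(runs[[v]]$by_sex))) {
      ov <- topk_overlap(main_run$by_sex[[s]]$ranked,
                         runs[[v]]$by_sex[[s]]$ranked)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, sex = s, overlap = ov$overlap, k = ov$k,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(runs = runs, overlap = do.call(rbind, rows)),
            class = "sensitivity_suite")
}
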