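#' Planted-combination recovery study
#'
#' Repeatedly generates cohorts from the `"recovery"` preset (two planted
#' synergistic pairs with a 20 kg extra grip decrement, 20,000 participants
#' per sex), runs the female-side ensemble analysis, and records for each
#' planted pair whether its exact positive-literal condition set ranks in
#' the top-k by composite score. The female side is used because both
#' planted pairs have workable joint prevalence there.
#'
#' @param n_seeds Number of generator seeds.
#' @param n_trees Ensemble size per seed.
#' @param k Top-k cut.
#' @param seed Master seed from which the generator seeds are spawned.
#' @param n_per_sex Cohort size per sex.
#' @return A list: `hits` (matrix, seeds x pairs, logical), `recovery_rate`
#'   (per-pair proportion of seeds recovered), `pairs`.
#' @export
recovery_study <- function(n_seeds = 20L, n_trees = 200L, k = 12L, seed = 1L,
                           n_per_sex = 20000L) {
  cfg <- sim_preset("recovery", sexes = "female", n_per_sex = n_per_sex)
  pairs <- cfg$synergy_effects_kg
  pair_keys <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "+")
  registry <- load_registry()
  reg_f <- registry_for_sex(registry, "female")
  set.seed(as.integer(seed))
  gen_seeds <- sample.int(.Machine$integer.max, n_seeds)
  hits <- matrix(NA, n_seeds, nrow(pairs),
                 dimnames = list(NULL, pair_keys))
  for (i in seq_len(n_seeds)) {
    sim <- generate_cohort(cfg, gen_seeds[i])
    an <- restrict_to_mltc(classify_sarcopenia_risk(
      validate_cohort(sim$cohort, reg_f)))
    ens <- bootstrap_ensemble(an, reg_f, n_trees = n_trees,
                              seed = gen_seeds[i])
    ranked <- rank_and_retain(composite_scores(ens), k)
    top_keys <- vapply(ranked$conditions[ranked$retained], paste,
                       character(1), collapse = "+")
    hits[i, ] <- pair_keys %in% top_keys
  }
  list(hits = hits, recovery_rate = colMeans(hits), pairs = pairs)
}

#' Interval-coverage study for the RERI estimator
#'
#' Computes the true odds-scale RERI of the planted pair of the `"coverage"`
#' preset with the Monte-Carlo oracle, then generates `n_rep` cohorts,
#' estimates the pair's RERI with a delta-method 95% interval in each, and
#' reports how often the interval covers the truth. The odds scale is used
#' for the truth because the logistic estimator targets the odds-ratio-based
#' contrast (see [true_pair_reri()]).
#'
#' @param n_rep Number of replicate cohorts.
#' @param seed Master seed (spawns one generator seed per replicate; the
#'   oracle uses its own derived seed).
#' @param n_mc_oracle Monte-Carlo draws for the truth.
#' @return A list: `coverage` (fraction in `[0, 1]`), `true_reri`,
#'   `estimates` (per-replicate RERI), `covered` (logical vector).
#' @export
coverage_study <- function(n_rep = 500L, seed = 1L, n_mc_oracle = 2e6) {
  cfg <- sim_preset("coverage")
  pair <- c("diabetes", "osteoarthritis")
  reg <- as_registry(data.frame(
    condition_id = cfg$prevalence$condition_id,
    display_name = cfg$prevalence$condition_id,
    sex_restricted = NA_character_, stringsAsFactors = FALSE))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_rep + 1L)
  truth <- true_pair_reri(cfg, pair, "male", scale = "or",
                          n_mc = n_mc_oracle, seed = seeds[n_rep + 1L])
  est <- numeric(n_rep)
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- generate_cohort(cfg, seeds[i])
    an <- restrict_to_mltc(classify_sarcopenia_risk(
      validate_cohort(sim$cohort, reg)))
    rr <- reri(joint_exposure_ors(an, pair[1], pair[2]))
    est[i] <- rr$reri
    covered[i] <- rr$ci[1] <= truth$reri && truth$reri <= rr$ci[2]
  }
  list(coverage = mean(covered), true_reri = truth$reri,
       estimates = est, covered = covered)
}
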