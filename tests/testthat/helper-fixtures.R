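# Shared fixtures: small registries and cohorts built in code.

tiny_registry <- function(ids = c("diabetes", "osteoarthritis", "stroke",
                                  "hypertension")) {
  sarcomb:::as_registry(data.frame(
    condition_id = ids, display_name = ids,
    sex_restricted = NA_character_, stringsAsFactors = FALSE))
}

# Deterministic cohort: n participants of one sex, explicit indicators/grip.
manual_cohort <- function(sex, grip, conditions, unable = FALSE,
                          age = 60) {
  n <- length(grip)
  df <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = rep_len(sex, n), age_years = rep_len(age, n),
    grip_max_kg = grip, unable_health = rep_len(unable, n),
    stringsAsFactors = FALSE)
  for (id in names(conditions)) df[[id]] <- rep_len(conditions[[id]], n)
  df
}

# Full 53-condition prevalence table with every prevalence set to zero.
default_prevalence_zeroed <- function() {
  prev <- sarcomb:::default_prevalence()
  prev$female <- 0
  prev$male <- 0
  prev
}

# Random binary dataset with a monotone logit signal, for tree tests.
random_binary_dataset <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("c", seq_len(p))))
  beta <- sample(c(-1.5, -0.5, 0.5, 1.5), p, replace = TRUE)
  eta <- X %*% beta - mean(X %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y)
}

# Cohort whose exposure/outcome cross-tabulations are given exactly by counts:
# counts is a data.frame with indicator columns plus `at_risk` and `n`.
cohort_from_counts <- function(counts, sex = "female") {
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), , drop = FALSE]
  rows$n <- NULL
  at_risk <- as.logical(rows$at_risk)
  rows$at_risk <- NULL
  df <- data.frame(
    participant_id = sprintf("P%05d", seq_len(nrow(rows))),
    sex = sex, age_years = 60,
    grip_max_kg = ifelse(at_risk, 10, 50),  # consistent with classification
    unable_health = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, rows)
  df$at_risk <- at_risk
  df$n_ltc <- as.integer(rowSums(rows))
  rownames(df) <- NULL
  df
}

# Small simulated analytic cohort (single sex) for ensemble-level tests.
simulated_analytic <- function(n_per_sex = 3000L, seed = 42L,
                               sexes = "female", preset = "ukb_like", ...) {
  cfg <- sim_preset(preset, n_per_sex = n_per_sex, sexes = sexes, ...)
  full <- load_registry()
  reg <- sarcomb:::as_registry(
    full[full$condition_id %in% cfg$prevalence$condition_id, , drop = FALSE])
  sim <- generate_cohort(cfg, seed)
  an <- restrict_to_mltc(classify_sarcopenia_risk(
    validate_cohort(sim$cohort, reg)))
  list(cohort = an, registry = reg, config = cfg)
}
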