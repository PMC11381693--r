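#' Simulation configuration for synthetic multimorbid cohorts
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: sex-stratified prevalences of binary long-term conditions
#' (independent draws by default, or a thresholded latent-Gaussian copula when
#' a dependence matrix is given), uniform ages, and a continuous latent grip
#' strength built from a sex-specific intercept, a linear age slope, additive
#' per-condition decrements, extra decrements for planted synergistic pairs,
#' and Gaussian noise. Sarcopenia risk arises downstream by thresholding grip,
#' so planted pairs have a well-defined true additive interaction that
#' [true_pair_reri()] computes by Monte-Carlo integration.
#'
#' @param n_per_sex Number of participants generated per sex (scalar, or a
#'   named vector `c(female=, male=)`).
#' @param sexes Which sexes to generate (default both).
#' @param age_range_years Uniform age range `(low, high)`.
#' @param prevalence Data frame with columns `condition_id`, `female`, `male`
#'   giving per-sex condition probabilities.
#' @param dependence Optional condition-by-condition latent correlation matrix
#'   (positive semi-definite, matching `prevalence` order); `NULL` means
#'   independent conditions.
#' @param intercept_kg Named vector `c(female=, male=)`: grip intercept at the
#'   lower age bound with no conditions.
#' @param age_slope_kg_per_year Grip decline per year of age.
#' @param main_effects_kg Named vector of per-condition mean grip decrements
#'   (kg); conditions absent from the vector get `default_effect_kg`.
#' @param default_effect_kg Decrement for conditions without a specific entry.
#' @param synergy_effects_kg Data frame with columns `a`, `b`, `effect_kg`:
#'   extra decrement applied when both conditions of a pair are present.
#' @param noise_sd_kg Residual SD of grip (scalar or named per-sex vector).
#' @param unable_rate Probability of being unable to perform the grip test
#'   for health reasons (grip then missing).
#' @return A list of class `simulation_config`.
#' @seealso [sim_preset()] for packaged calibrations.
#' @export
simulation_config <- function(n_per_sex = 5000L,
                              sexes = c("female", "male"),
                              age_range_years = c(40, 70),
                              prevalence = default_prevalence(),
                              dependence = NULL,
                              intercept_kg = c(female = 28.2, male = 44.8),
                              age_slope_kg_per_year = 0.08,
                              main_effects_kg = default_main_effects(),
                              default_effect_kg = 1.0,
                              synergy_effects_kg = NULL,
                              noise_sd_kg = c(female = 6.4, male = 9.0),
                              unable_rate = 0.0012) {
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  stopifnot(is.data.frame(prevalence),
            all(c("condition_id", "female", "male") %in% names(prevalence)))
  pv <- c(prevalence$female, prevalence$male)
  if (anyNA(pv) || any(pv < 0 | pv > 1)) stop("prevalences must be in [0, 1]")
  if (length(n_per_sex) == 1L && is.null(names(n_per_sex))) {
    n_per_sex <- stats::setNames(rep(as.integer(n_per_sex), length(sexes)), sexes)
  }
  noise_sd_kg <- expand_by_sex(noise_sd_kg, sexes, "noise_sd_kg")
  if (any(noise_sd_kg <= 0)) stop("noise_sd_kg must be strictly positive")
  intercept_kg <- expand_by_sex(intercept_kg, sexes, "intercept_kg")
  if (!is.null(dependence)) {
    dependence <- as.matrix(dependence)
    if (!isSymmetric(unname(dependence)) ||
        nrow(dependence) != nrow(prevalence)) {
      stop("dependence must be a symmetric matrix matching the prevalence table")
    }
    if (min(eigen(dependence, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("dependence matrix is not positive semi-definite")
    }
  }
  if (!is.null(synergy_effects_kg)) {
    stopifnot(is.data.frame(synergy_effects_kg),
              all(c("a", "b", "effect_kg") %in% names(synergy_effects_kg)))
    ids <- prevalence$condition_id
    ref <- c(synergy_effects_kg$a, synergy_effects_kg$b)
    if (!all(ref %in% ids)) {
      stop("synergy pair references unknown condition: ",
           paste(setdiff(ref, ids), collapse = ", "))
    }
    # a pair that can never co-occur in any generated sex is a config error
    for (i in seq_len(nrow(synergy_effects_kg))) {
      a <- synergy_effects_kg$a[i]; b <- synergy_effects_kg$b[i]
      pa <- prevalence[match(a, ids), sexes, drop = FALSE]
      pb <- prevalence[match(b, ids), sexes, drop = FALSE]
      if (all(unlist(pa) * unlist(pb) == 0)) {
        stop("synergy pair (", a, ", ", b, ") has zero joint prevalence in ",
             "every generated sex (sex-restricted or zero-prevalence condition)")
      }
    }
  }
  # per-condition effect vector in prevalence order
  eff <- stats::setNames(rep(default_effect_kg, nrow(prevalence)),
                         prevalence$condition_id)
  known <- intersect(names(main_effects_kg), names(eff))
  eff[known] <- main_effects_kg[known]
  structure(list(n_per_sex = n_per_sex, sexes = sexes,
                 age_range_years = age_range_years,
                 prevalence = prevalence, dependence = dependence,
                 intercept_kg = intercept_kg,
                 age_slope_kg_per_year = age_slope_kg_per_year,
                 main_effects_kg = eff,
                 synergy_effects_kg = synergy_effects_kg,
                 noise_sd_kg = noise_sd_kg, unable_rate = unable_rate),
            class = "simulation_config")
}

expand_by_sex <- function(x, sexes, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(x, length(sexes)), sexes))
  }
  if (!all(sexes %in% names(x))) stop(what, " must name every generated sex")
  x[sexes]
}

#' Packaged simulation presets
#'
#' * `"ukb_like"` — per-sex condition prevalences matching a large UK
#'   population cohort of adults in mid and later life (the calibration
#'   table spans roughly 0.02%–67%), grip intercepts and noise giving mean
#'   grip near 23 kg (women) / 39 kg (men) and an at-risk fraction near
#'   20–25% after multimorbidity restriction; 5000 participants per sex for
#'   fast tests; no planted synergies.
#' * `"paper_scale"` — the same calibration at full cohort scale
#'   (77,488 women / 62,513 men).
#' * `"recovery"` — `ukb_like` at 20,000 per sex with two planted synergistic
#'   pairs, each with a 20 kg extra decrement: diabetes with osteoarthritis,
#'   and connective tissue disease with osteoporosis. Used by the
#'   planted-combination recovery study.
#' * `"coverage"` — a reduced six-condition, male-only configuration with one
#'   planted pair (diabetes and osteoarthritis, 5 kg extra decrement), used
#'   by the interval-coverage study for the additive-interaction estimator.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A `simulation_config`.
#' @export
sim_preset <- function(name = c("ukb_like", "paper_scale", "recovery", "coverage"),
                       ...) {
  name <- match.arg(name)
  overrides <- list(...)
  args <- switch(name,
    ukb_like = list(),
    paper_scale = list(n_per_sex = c(female = 77488L, male = 62513L)),
    recovery = list(
      n_per_sex = 20000L,
      synergy_effects_kg = data.frame(
        a = c("diabetes", "connective_tissue_disease"),
        b = c("osteoarthritis", "osteoporosis"),
        effect_kg = c(20, 20))),
    coverage = list(
      n_per_sex = 20000L, sexes = "male",
      prevalence = data.frame(
        condition_id = c("diabetes", "osteoarthritis", "hypertension",
                         "copd", "stroke", "depression"),
        female = c(0.1085, 0.2668, 0.5271, 0.0634, 0.0333, 0.1658),
        male   = c(0.2143, 0.1738, 0.6720, 0.0737, 0.0590, 0.1077)),
      intercept_kg = c(male = 45),
      main_effects_kg = c(diabetes = 2, osteoarthritis = 2, hypertension = 0.5,
                          copd = 2, stroke = 3, depression = 1),
      synergy_effects_kg = data.frame(a = "diabetes", b = "osteoarthritis",
                                      effect_kg = 5),
      noise_sd_kg = c(male = 9))
  )
  args[names(overrides)] <- overrides
  do.call(simulation_config, args)
}

#' Default per-sex condition prevalences (fractions) for the ukb-like presets
#' @noRd
default_prevalence <- function() {
  reg <- load_registry()
  f <- c(0.0333, 0.0743, 0.0014, 0.0066, 0.0217, 0.0300, 0.0732, 0.0002,
         0.5271, 0.1085, 0.0013, 0.2171, 0.0634, 0.2747, 0.0080, 0.0028,
         0.0175, 0.0098, 0.0105, 0.0091, 0.0032, 0.0070, 0.1931, 0.0094,
         0.0005, 0.0181, 0.0009, 0.0005, 0.0018, 0.1658, 0.0409, 0.0071,
         0.0023, 0.0032, 0.0018, 0.0631, 0.2668, 0.0563, 0.0663, 0.0062,
         0.0130, 0.0195, 0.0052, 0.0227, 0.0070, 0.0013, 0.0333, 0.0385,
         0.0432, 0.0079, 0.0006, 0.0130, 0.0015)
  m <- c(0.0590, 0.2065, 0.0031, 0.0081, 0.0181, 0.0515, 0.0617, 0.0013,
         0.6720, 0.2143, 0.0008, 0.0520, 0.0737, 0.2253, 0.0047, 0.0054,
         0.0207, 0.0042, 0.0155, 0.0122, 0.0048, 0.0011, 0.1258, 0.0147,
         0.0004, 0.0154, 0.0004, 0.0009, 0.0043, 0.1077, 0.0279, 0.0067,
         0.0083, 0.0003, 0.0021, 0.0322, 0.1738, 0.0730, 0.0116, 0.0791,
         0.0155, 0.0193, 0.0067, 0.0379, 0.0089, 0.0025, 0.0000, 0.0149,
         0.0620, 0.0053, 0.0043, 0.0130, 0.0018)
  data.frame(condition_id = reg$condition_id, female = f, male = m,
             stringsAsFactors = FALSE)
}

#' Per-condition grip decrements (kg); neurological/severe conditions larger
#' @noRd
default_main_effects <- function() {
  c(stroke = 3, heart_failure = 3, paralysis = 5, multiple_sclerosis = 4,
    parkinsons_disease = 4, dementia = 4, metastatic_cancers = 4,
    end_stage_kidney_disease = 3, copd = 2, osteoporosis = 2,
    connective_tissue_disease = 2.5, osteoarthritis = 2, diabetes = 1.5,
    solid_organ_cancers = 1.5, chronic_primary_pain = 2)
}

#' Generate a synthetic cohort
#'
#' Draws a participant table in the cohort dialect from a
#' [simulation_config()]. Conditions are sampled independently per sex at the
#' configured prevalences (or through a thresholded latent Gaussian copula
#' when `dependence` is given); latent grip is
#' `intercept - slope * (age - age_low) - sum(main effects) - sum(synergy
#' effects) + N(0, sd)`; the "unable for health reasons" flag is set uniformly
#' at random at `unable_rate`, with grip then missing. Output is reproducible
#' given `seed`.
#'
#' @param cfg A `simulation_config`.
#' @param seed Integer seed (mandatory; there is no silent default RNG state).
#' @return A list with `cohort` (unrestricted, unclassified cohort data frame
#'   including `n_ltc`) and `ground_truth` (planted pairs, the grip model, and
#'   the configuration; pass to [true_pair_reri()] for true interaction
#'   values).
#' @export
generate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (missing(seed)) stop("seed is mandatory")
  ids <- cfg$prevalence$condition_id
  set.seed(as.integer(seed))
  parts <- lapply(cfg$sexes, function(sex) {
    n <- cfg$n_per_sex[[sex]]
    p <- cfg$prevalence[[sex]]
    X <- draw_conditions(n, p, cfg$dependence)
    colnames(X) <- ids
    age <- stats::runif(n, cfg$age_range_years[1], cfg$age_range_years[2])
    mu <- grip_mean(cfg, sex, age, X)
    grip <- mu + stats::rnorm(n, 0, cfg$noise_sd_kg[[sex]])
    unable <- stats::runif(n) < cfg$unable_rate
    grip[unable] <- NA_real_
    grip <- round(grip, 1)
    grip[!is.na(grip) & grip < 0] <- 0  # dynamometer floor
    df <- data.frame(
      participant_id = sprintf("%s%06d", toupper(substr(sex, 1, 1)), seq_len(n)),
      sex = sex, age_years = round(age, 1), grip_max_kg = grip,
      unable_health = unable, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(X))
  })
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  cohort$n_ltc <- as.integer(rowSums(cohort[ids]))
  ground_truth <- list(
    planted_pairs = cfg$synergy_effects_kg,
    grip_model = list(intercept_kg = cfg$intercept_kg,
                      age_slope_kg_per_year = cfg$age_slope_kg_per_year,
                      main_effects_kg = cfg$main_effects_kg,
                      noise_sd_kg = cfg$noise_sd_kg),
    config = cfg, seed = as.integer(seed))
  list(cohort = cohort, ground_truth = ground_truth)
}

draw_conditions <- function(n, p, dependence = NULL) {
  k <- length(p)
  if (is.null(dependence)) {
    X <- matrix(stats::runif(n * k) < rep(p, each = n), n, k)
  } else {
    L <- chol(dependence + diag(1e-10, k))
    Z <- matrix(stats::rnorm(n * k), n, k) %*% L
    X <- sweep(Z, 2, stats::qnorm(p), "<")
  }
  storage.mode(X) <- "integer"
  X
}

grip_mean <- function(cfg, sex, age, X) {
  eff <- cfg$main_effects_kg[colnames(X)]
  mu <- cfg$intercept_kg[[sex]] -
    cfg$age_slope_kg_per_year * (age - cfg$age_range_years[1]) -
    as.vector(X %*% eff)
  syn <- cfg$synergy_effects_kg
  if (!is.null(syn)) {
    for (i in seq_len(nrow(syn))) {
      both <- X[, syn$a[i]] * X[, syn$b[i]]
      mu <- mu - syn$effect_kg[i] * both
    }
  }
  mu
}

#' True additive interaction of a condition pair under a simulation config
#'
#' Monte-Carlo oracle for the relative excess risk due to interaction (RERI)
#' implied by a generator configuration: draws a large synthetic population of
#' the given sex, applies the multimorbidity restriction, computes each
#' individual's exact at-risk probability by integrating the Gaussian grip
#' noise in closed form (`unable_rate + (1 - unable_rate) *
#' pnorm((threshold - mu) / sd)`), and averages within the four exposure cells
#' of the pair. On the `"rr"` scale the oracle returns
#' `RR11 - RR10 - RR01 + 1` with risks relative to the doubly-unexposed cell;
#' on the `"or"` scale cell odds replace cell risks, matching the estimand of
#' the logistic-regression RERI estimator (odds ratios are only
#' approximately risk ratios when the outcome is common).
#'
#' @param cfg A `simulation_config` (or the `ground_truth$config` of a
#'   generated cohort).
#' @param pair Character vector of two condition ids.
#' @param sex `"female"` or `"male"`.
#' @param cls Classification config supplying the grip threshold.
#' @param scale `"rr"` (risk-ratio) or `"or"` (odds-ratio) contrast scale.
#' @param min_ltc Multimorbidity restriction applied before averaging.
#' @param n_mc Number of Monte-Carlo draws (before restriction).
#' @param seed Seed for the oracle's own RNG stream.
#' @return List with `reri`, `mc_se` (batch-based Monte-Carlo standard
#'   error), `cell_risks` and `cell_n` (named `r00`, `r10`, `r01`, `r11`).
#' @export
true_pair_reri <- function(cfg, pair, sex, cls = classification_config(),
                           scale = c("rr", "or"), min_ltc = 2L,
                           n_mc = 1e6, seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  ids <- cfg$prevalence$condition_id
  if (!all(pair %in% ids)) stop("pair not in configured conditions")
  if (!sex %in% cfg$sexes) stop("sex not generated by this config")
  thr <- if (sex == "male") cls$male_threshold_kg else cls$female_threshold_kg
  sd <- cfg$noise_sd_kg[[sex]]
  p <- cfg$prevalence[[sex]]

  n_batch <- 10L
  per <- ceiling(n_mc / n_batch)
  cells <- c("r00", "r10", "r01", "r11")
  batch_reri <- numeric(n_batch)
  tot_sum <- stats::setNames(numeric(4), cells)
  tot_n <- stats::setNames(numeric(4), cells)
  set.seed(as.integer(seed))
  for (b in seq_len(n_batch)) {
    X <- draw_conditions(per, p, cfg$dependence)
    colnames(X) <- ids
    age <- stats::runif(per, cfg$age_range_years[1], cfg$age_range_years[2])
    mu <- grip_mean(cfg, sex, age, X)
    risk <- cfg$unable_rate +
      (1 - cfg$unable_rate) * stats::pnorm((thr - mu) / sd)
    keep <- rowSums(X) >= min_ltc
    cell <- paste0("r", X[keep, pair[1]], X[keep, pair[2]])
    cell <- factor(cell, levels = c("r00", "r10", "r01", "r11"))
    s <- tapply(risk[keep], cell, sum, default = 0)
    n <- tabulate(cell, 4)
    tot_sum <- tot_sum + s
    tot_n <- tot_n + n
    if (any(n == 0)) {
      batch_reri[b] <- NA_real_
    } else {
      batch_reri[b] <- reri_from_cell_risks(s / n, scale)
    }
  }
  if (any(tot_n == 0)) {
    stop("exposure cell with zero probability mass for pair (",
         pair[1], ", ", pair[2], "): RERI undefined")
  }
  cell_risks <- tot_sum / tot_n
  list(reri = reri_from_cell_risks(cell_risks, scale),
       mc_se = stats::sd(batch_reri, na.rm = TRUE) / sqrt(sum(!is.na(batch_reri))),
       cell_risks = cell_risks, cell_n = tot_n, scale = scale)
}

reri_from_cell_risks <- function(r, scale) {
  if (scale == "or") {
    contrast <- (r / (1 - r)) / (r[["r00"]] / (1 - r[["r00"]]))
  } else {
    contrast <- r / r[["r00"]]
  }
  unname(contrast[["r11"]] - contrast[["r10"]] - contrast[["r01"]] + 1)
}

#' Round-trip a simulation config through YAML
#'
#' @param cfg A `simulation_config`.
#' @param path Output YAML path.
#' @export
write_simulation_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$prevalence <- as.list(x$prevalence)
  if (!is.null(x$synergy_effects_kg)) {
    x$synergy_effects_kg <- as.list(x$synergy_effects_kg)
  }
  # named atomic vectors must become maps, or YAML drops the names
  for (f in c("main_effects_kg", "n_per_sex", "intercept_kg", "noise_sd_kg")) {
    x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_config(
    n_per_sex = unlist(x$n_per_sex), sexes = unlist(x$sexes),
    age_range_years = unlist(x$age_range_years),
    prevalence = as.data.frame(x$prevalence, stringsAsFactors = FALSE),
    dependence = if (is.null(x$dependence)) NULL else
      do.call(rbind, lapply(x$dependence, unlist)),
    intercept_kg = unlist(x$intercept_kg),
    age_slope_kg_per_year = x$age_slope_kg_per_year,
    main_effects_kg = unlist(x$main_effects_kg),
    synergy_effects_kg = if (is.null(x$synergy_effects_kg)) NULL else
      as.data.frame(x$synergy_effects_kg, stringsAsFactors = FALSE),
    noise_sd_kg = unlist(x$noise_sd_kg),
    unable_rate = x$unable_rate)
}
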