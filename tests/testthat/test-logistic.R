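test_that("a single-exposure fit recovers the closed-form 2x2 odds ratio", {
  # exposure x outcome table [[30, 70], [10, 90]] -> OR = 30*90 / (70*10)
  co <- cohort_from_counts(data.frame(
    diabetes = c(1, 1, 0, 0), at_risk = c(1, 0, 1, 0),
    n = c(30, 70, 10, 90)))
  f <- fit_logistic(co, "diabetes")
  expect_equal(f$or$or[f$or$term == "diabetes"], 30 * 90 / (70 * 10),
               tolerance = 1e-6)
  expect_true(f$converged)
  expect_false(f$separation_flag)
})

test_that("a null association gives OR near 1 with a covering CI", {
  set.seed(3)
  co <- cohort_from_counts(data.frame(
    diabetes = c(1, 1, 0, 0), at_risk = c(1, 0, 1, 0),
    n = c(400, 1600, 400, 1600)))
  f <- fit_logistic(co, "diabetes")
  row <- f$or[f$or$term == "diabetes", ]
  expect_equal(row$or, 1, tolerance = 1e-6)
  expect_true(row$ci_low <= 1 && 1 <= row$ci_high)
})

test_that("complete separation is flagged rather than silently reported", {
  co <- cohort_from_counts(data.frame(
    diabetes = c(1, 0), at_risk = c(1, 0), n = c(60, 60)))
  f <- suppressWarnings(fit_logistic(co, "diabetes"))
  expect_true(f$separation_flag)
})

test_that("joint-exposure odds ratios reproduce saturated cell-count ORs", {
  counts <- data.frame(
    diabetes = c(0, 0, 1, 1, 0, 0, 1, 1),
    stroke   = c(0, 0, 0, 0, 1, 1, 1, 1),
    at_risk  = c(1, 0, 1, 0, 1, 0, 1, 0),
    n        = c(100, 900, 80, 320, 60, 240, 90, 110))
  co <- cohort_from_counts(counts)
  jo <- joint_exposure_ors(co, "diabetes", "stroke")
  odds <- function(a, b) a / b
  o00 <- odds(100, 900)
  expect_equal(jo$or10$or, odds(80, 320) / o00, tolerance = 1e-6)
  expect_equal(jo$or01$or, odds(60, 240) / o00, tolerance = 1e-6)
  expect_equal(jo$or11$or, odds(90, 110) / o00, tolerance = 1e-6)
  expect_error(joint_exposure_ors(co, "diabetes", "diabetes"), "must differ")

  # empty exposure cell is named in the error
  co2 <- co[!(co$diabetes == 1 & co$stroke == 1), ]
  expect_error(joint_exposure_ors(co2, "diabetes", "stroke"), "empty exposure cell")
})

test_that("RERI point estimates satisfy the additive-scale identity", {
  expect_equal(reri(c(or10 = 1, or01 = 1, or11 = 1))$reri, 0)
  expect_equal(reri(c(or10 = 2, or01 = 3, or11 = 4))$reri, 0)  # exact additivity
  expect_equal(reri(c(or10 = 1.11, or01 = 1.31, or11 = 4.74))$reri, 3.32,
               tolerance = 1e-12)
  expect_error(reri(c(1, 2)), "three odds ratios")

  counts <- data.frame(
    diabetes = c(0, 0, 1, 1, 0, 0, 1, 1),
    stroke   = c(0, 0, 0, 0, 1, 1, 1, 1),
    at_risk  = c(1, 0, 1, 0, 1, 0, 1, 0),
    n        = c(100, 900, 80, 320, 60, 240, 90, 110))
  co <- cohort_from_counts(counts)
  jo <- joint_exposure_ors(co, "diabetes", "stroke")
  rr <- reri(jo)
  expect_identical(rr$reri, jo$or11$or - jo$or10$or - jo$or01$or + 1)
  expect_length(rr$ci, 2L)
  expect_lt(rr$ci[1], rr$reri)
  expect_gt(rr$ci[2], rr$reri)
})

test_that("delta and bootstrap intervals agree on well-behaved data", {
  sim <- simulated_analytic(n_per_sex = 6000L, seed = 15, sexes = "male",
                            preset = "coverage")
  jo <- joint_exposure_ors(sim$cohort, "diabetes", "osteoarthritis")
  delta <- reri(jo)
  boot <- reri(jo, method = "bootstrap", cohort = sim$cohort,
               n_boot = 200, seed = 8)
  expect_equal(delta$reri, boot$reri)
  # interval endpoints within each other's half-width
  hw <- (delta$ci[2] - delta$ci[1]) / 2
  expect_lt(abs(delta$ci[1] - boot$ci[1]), hw)
  expect_lt(abs(delta$ci[2] - boot$ci[2]), hw)
})

test_that("stratum odds ratios equal hand-computed per-stratum 2x2 ORs", {
  counts <- data.frame(
    diabetes = c(0, 0, 1, 1, 0, 0, 1, 1),
    stroke   = c(0, 0, 0, 0, 1, 1, 1, 1),
    at_risk  = c(1, 0, 1, 0, 1, 0, 1, 0),
    n        = c(100, 900, 80, 320, 60, 240, 90, 110))
  co <- cohort_from_counts(counts)
  st <- stratified_ors(co, "diabetes", "stroke")
  # OR of diabetes within stroke == 1: (90/110) / (60/240)
  or_in <- st[st$exposure == "diabetes" & st$stratum == "stroke = 1", "or"]
  expect_equal(or_in, (90 / 110) / (60 / 240), tolerance = 1e-6)
  or_out <- st[st$exposure == "diabetes" & st$stratum == "stroke = 0", "or"]
  expect_equal(or_out, (80 / 320) / (100 / 900), tolerance = 1e-6)
  # empty stratum is reported missing with a reason
  co2 <- co[co$stroke == 0, ]
  st2 <- stratified_ors(co2, "diabetes", "stroke")
  expect_true(is.na(st2[st2$stratum == "stroke = 1", "or"][1]))
  expect_match(st2[st2$stratum == "stroke = 1", "note"][1], "no variation")
})

test_that("age adjustment leaves ORs unchanged when age is independent", {
  sim <- simulated_analytic(n_per_sex = 8000L, seed = 19, sexes = "male",
                            preset = "coverage")
  # conditions are drawn independently of age in the generator
  f0 <- fit_logistic(sim$cohort, "diabetes")
  f1 <- fit_logistic(sim$cohort, "diabetes", adjust_age = TRUE)
  row0 <- f0$or[f0$or$term == "diabetes", ]
  row1 <- f1$or[f1$or$term == "diabetes", ]
  expect_lt(abs(row1$or - row0$or), (row0$ci_high - row0$ci_low) / 2)
})

test_that("triangulation dispatches by combination size", {
  sim <- simulated_analytic(n_per_sex = 5000L, seed = 23)
  recs <- structure(data.frame(
    label = c("connective_tissue_disease and any other LTC",
              "diabetes and osteoarthritis",
              "diabetes and hypertension and osteoarthritis"),
    n_trees_appearing = c(3L, 2L, 1L), n_leaves = 1L,
    composite_score = c(3, 2, 1), stringsAsFactors = FALSE),
    class = c("combination_records", "data.frame"))
  recs$conditions <- list("connective_tissue_disease",
                          c("diabetes", "osteoarthritis"),
                          c("diabetes", "hypertension", "osteoarthritis"))
  attr(recs, "n_trees") <- 3L
  ranked <- suppressWarnings(rank_and_retain(recs, k = 12))
  tri <- triangulate(sim$cohort, ranked)
  per <- tri$per_combination
  expect_length(per, 3L)
  # singleton: per-condition OR only
  expect_null(per[[1]]$reri)
  expect_equal(nrow(per[[1]]$condition_ors), 1L)
  # pair: joint ORs + RERI + strata
  expect_s3_class(per[[2]]$reri, "reri_estimate")
  expect_equal(nrow(per[[2]]$strata), 4L)
  # triple: per-condition ORs + all-present joint OR, no RERI
  expect_null(per[[3]]$reri)
  expect_equal(nrow(per[[3]]$condition_ors), 3L)
  expect_false(is.null(per[[3]]$joint_exposure_or))
  expect_gte(tri$n_tests, 6L)
  tab <- triangulation_table(tri)
  expect_true(all(c("condition_or", "joint_or", "reri") %in% tab$quantity))
})
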