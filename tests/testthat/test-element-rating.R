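# The five element raters and their composition.

test_that("the solution ladder maps categories to alternative ratings", {
  expect_equal(rate_alternative_product("generic_substitution"), 1L)
  expect_equal(rate_alternative_product("therapeutic_substitution"), 2L)
  expect_equal(rate_alternative_product("unlicensed_product"), 2L)
  expect_equal(rate_alternative_product("no_therapy"), 3L)
  expect_error(rate_alternative_product("compounding"), "Unknown solution")
  # ladder is configurable
  cfg <- rater_config(solution_ladder = c(
    generic_substitution = 1L, therapeutic_substitution = 2L,
    unlicensed_product = 3L, no_therapy = 3L))
  expect_equal(rate_alternative_product("unlicensed_product", cfg), 3L)
})

test_that("disease rating handles enumerants and disability weights", {
  expect_equal(rate_disease(c("mild", "moderate", "severe", "multi_class")),
               c(1L, 2L, 3L, 2L))
  # numeric weights through the default cutpoints (<=0.10, >0.30)
  expect_equal(rate_disease(c("0.05", "0.10", "0.2", "0.30", "0.305", "0.95")),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(rate_disease(0.95), 3L)
  expect_error(rate_disease("1.5"), "\\[0, 1\\]")
  expect_error(rate_disease("critical"), "Unknown disease_severity")
})

test_that("susceptibility is the max of vulnerability and trust aspects", {
  # adults only, no flags -> all low
  r <- rate_susceptibility(25, 60)
  expect_equal(r$susceptibility, 1L)
  # media attention alone lifts the element to high
  r <- rate_susceptibility(25, 60, media_attention = TRUE)
  expect_equal(unlist(r), c(vulnerability = 1L, trust = 3L, susceptibility = 3L))
  # child-only population is highly vulnerable
  expect_equal(rate_susceptibility(0, 12)$susceptibility, 3L)
  expect_equal(rate_susceptibility(0, 12)$vulnerability, 3L)
  # elderly-only population likewise
  expect_equal(rate_susceptibility(70, 95)$vulnerability, 3L)
  # children or elderly among adults rate moderate
  expect_equal(rate_susceptibility(10, 60)$vulnerability, 2L)
  expect_equal(rate_susceptibility(30, 80)$vulnerability, 2L)
  # patient-contact notes alone rate trust moderate
  expect_equal(rate_susceptibility(25, 60,
                                   patient_contact_notes = TRUE)$trust, 2L)
  expect_equal(rate_susceptibility(25, 60,
                                   patient_forum_reports = TRUE)$trust, 3L)
  expect_error(rate_susceptibility(60, 25), "age_min")
})

test_that("cost thresholds are the type-7 quartiles of the cohort ratios", {
  th <- compute_cost_thresholds(c(50, 80, 100, 120, 300))
  expect_equal(th$q1, 80)
  expect_equal(th$q3, 120)
  expect_equal(th$median, 100)
  # degenerate spread collapses both quartiles
  th0 <- compute_cost_thresholds(rep(100, 6))
  expect_equal(c(th0$q1, th0$q3), c(100, 100))
  # fewer than 4 ratios is an error instructing explicit thresholds
  expect_error(compute_cost_thresholds(c(100, 200)),
               "explicit", class = "cost_threshold_error")
  expect_error(cost_thresholds(q1 = 120, q3 = 80), "q1")
})

test_that("costs element is max(medicine aspect, personnel aspect)", {
  th <- default_thresholds()
  # ratio 300 above q3 -> medicine 3 beats personnel 2
  r <- rate_costs(10, 30, th, alternative_rating = 2L)
  expect_equal(unlist(r),
               c(medicine_cost = 3L, personnel_cost = 2L, costs = 3L))
  # ratio 100 inside the IQR -> moderate medicine aspect dominates personnel 1
  r <- rate_costs(10, 10, th, alternative_rating = 1L)
  expect_equal(r$costs, 2L)
  # boundary ratios rate moderate (strict inequalities)
  expect_equal(rate_costs(100, 80, th, 1L)$medicine_cost, 2L)
  expect_equal(rate_costs(100, 120, th, 1L)$medicine_cost, 2L)
  expect_equal(rate_costs(100, 121, th, 1L)$medicine_cost, 3L)
  expect_equal(rate_costs(100, 79, th, 1L)$medicine_cost, 1L)
  # missing prices fall through to the personnel aspect
  r <- rate_costs(NA, NA, th, alternative_rating = 3L)
  expect_equal(r$costs, 3L)
  expect_true(is.na(r$medicine_cost))
  # zero original price: undefined ratio, warned and omitted
  expect_warning(r0 <- rate_costs(0, 10, th, 2L), "undefined")
  expect_equal(r0$costs, 2L)
})

test_that("number of patients: orphan overrides, hospital defaults moderate", {
  expect_equal(rate_n_patients(NA, hospital_product = TRUE), 2L)
  expect_equal(rate_n_patients(NA, orphan_indication = TRUE), 1L)
  expect_equal(rate_n_patients(NA, hospital_product = TRUE,
                               orphan_indication = TRUE), 1L)
  # counts through the default thresholds (<=1e3 low, >=1e5 high)
  expect_equal(rate_n_patients(c(500, 1000, 1001, 99999, 1e5, 5e5)),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  # a hospital product with usage statistics is rated from the count
  expect_equal(rate_n_patients(5e5, hospital_product = TRUE), 3L)
  expect_error(rate_n_patients(NA), "count", class = "rating_error")
})

test_that("rate_record composes the five raters and keeps aspects", {
  th <- default_thresholds()
  rec <- make_record(solution_category = "therapeutic_substitution",
                     disease_severity = "severe", age_min = 0, age_max = 12,
                     price_original = 10, price_alternative = 20,
                     hospital_product = TRUE, users_prior_year = NA_real_)
  p <- rate_record(rec, th)
  expect_s3_class(p, "element_profile")
  expect_equal(unname(p$ratings), c(2L, 3L, 3L, 3L, 2L))
  expect_equal(p$aspects$medicine_cost, 3L)
  expect_equal(p$aspects$personnel_cost, 2L)

  rec2 <- make_record(solution_category = "generic_substitution",
                      disease_severity = "mild", age_min = 25, age_max = 60,
                      price_original = 10, price_alternative = 10,
                      orphan_indication = TRUE)
  p2 <- rate_record(rec2, th)
  expect_equal(unname(p2$ratings), c(1L, 1L, 1L, 2L, 1L))

  # bypass mode: an existing profile passes through unchanged
  expect_identical(rate_record(p, th), p)

  # rater errors carry the element name
  bad <- make_record(users_prior_year = NA_real_)
  expect_error(rate_record(bad, th), "n_patients")
})

test_that("element profiles enforce the max-over-aspects invariant", {
  expect_error(element_profile(2, 3, 1, 2, 2,
                               aspects = list(vulnerability = 3, trust = 1)),
               "maximum of its aspect")
  expect_error(element_profile(2, 3, 3, 3, 2,
                               aspects = list(personnel_cost = 3)),
               "personnel_cost")
  expect_error(element_profile(2, NA, 1, 2, 2), class = "aggregation_error")
  expect_error(element_profile(2, 4, 1, 2, 2), "must be 1")
})

test_that("raising an aspect never lowers an element rating (property)", {
  th <- default_thresholds()
  set.seed(11)
  for (i in 1:200) {
    ages <- sort(sample(0:99, 2))
    flags <- runif(3) < 0.4
    base <- rate_susceptibility(ages[1], ages[2], flags[1], flags[2], flags[3])
    # lifting trust to its ceiling can only raise the element
    lifted <- rate_susceptibility(ages[1], ages[2], flags[1], TRUE, flags[3])
    expect_gte(lifted$susceptibility, base$susceptibility)
    expect_equal(base$susceptibility, max(base$vulnerability, base$trust))
    alt <- sample(1:3, 1)
    prices <- c(stats::runif(1, 1, 50), stats::runif(1, 1, 150))
    rc <- rate_costs(prices[1], prices[2], th, alt)
    expect_equal(rc$costs, max(rc$medicine_cost, rc$personnel_cost, na.rm = TRUE))
    rc3 <- rate_costs(prices[1], prices[2], th, 3L)
    expect_gte(rc3$costs, rc$costs)
  }
})

test_that("rate_cohort computes cohort-relative thresholds and is deterministic", {
  cohort <- make_cohort(
    list(price_original = 100, price_alternative = 50),
    list(price_original = 100, price_alternative = 80),
    list(price_original = 100, price_alternative = 100),
    list(price_original = 100, price_alternative = 120),
    list(price_original = 100, price_alternative = 300))
  scored <- rate_cohort(cohort)
  th <- attr(scored, "cost_thresholds")
  expect_equal(c(th$q1, th$q3), c(80, 120))
  expect_equal(scored$aspect_medicine_cost, c(1L, 2L, 2L, 2L, 3L))
  # at most 25% of ratios rate high and 25% low under empirical quartiles
  expect_lte(mean(scored$aspect_medicine_cost == 3L), 0.25)
  expect_lte(mean(scored$aspect_medicine_cost == 1L), 0.25)
  expect_identical(rate_cohort(cohort), scored)
  expect_error(rate_cohort(make_cohort(list())), class = "cost_threshold_error")
})

test_that("rater config round-trips through YAML and fingerprints stably", {
  cfg <- rater_config(child_age_max = 16, dunn_adjust = "holm")
  path <- withr::local_tempfile(fileext = ".yml")
  write_rater_config(cfg, path)
  back <- read_rater_config(path)
  expect_equal(back, cfg)
  expect_equal(config_fingerprint(back), config_fingerprint(cfg))
  expect_false(config_fingerprint(cfg) ==
                 config_fingerprint(rater_config()))
  expect_error(rater_config(disability_low_max = 0.5,
                            disability_high_min = 0.3), "disability")
})
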