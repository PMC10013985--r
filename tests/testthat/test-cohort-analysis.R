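# Sample-size calculation, characterisation, representativeness testing,
# stratified comparisons and distributions.

test_that("finite-population sample size reproduces the worked values", {
  expect_equal(required_sample_size(1844), 319L)
  expect_equal(required_sample_size(100), 80L)
  # as N grows the correction vanishes: ceil(1.959964^2 * 0.25 / 0.0025)
  expect_equal(required_sample_size(1e9), 385L)
  expect_error(required_sample_size(1844, margin = 0), "margin")
})

test_that("sample size is monotone in margin, population and confidence", {
  expect_lt(required_sample_size(1844, margin = 0.10),
            required_sample_size(1844, margin = 0.05))
  expect_lte(required_sample_size(500), required_sample_size(5000))
  expect_lte(required_sample_size(1844, confidence = 0.90),
             required_sample_size(1844, confidence = 0.95))
  # converges to the uncorrected n0 from below
  n0 <- ceiling(qnorm(0.975)^2 * 0.25 / 0.05^2)
  sizes <- vapply(c(1e3, 1e5, 1e7, 1e9), required_sample_size, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes[4], as.integer(n0))
})

test_that("draw_sample is seed-reproducible, without replacement", {
  g <- generate_cohort(generator_spec(n = 400, seed = 5))
  s1 <- draw_sample(g$cohort, 324, seed = 9)
  s2 <- draw_sample(g$cohort, 324, seed = 9)
  expect_equal(s1$records, s2$records)
  expect_equal(length(unique(s1$records$shortage_id)), 324)
  s3 <- draw_sample(g$cohort, 400, seed = 1)
  expect_setequal(s3$records$shortage_id, g$cohort$records$shortage_id)
  expect_error(draw_sample(g$cohort, 401), "Cannot sample")
})

test_that("characterize counts and percentages per variable", {
  cohort <- make_cohort(list(route = "oral"), list(route = "oral"),
                        list(route = "rectal"),
                        list(route = "parenteral", atc_code = "J01CA04"))
  ch <- characterize(cohort)
  oral <- ch[ch$variable == "route" & ch$category == "oral", ]
  expect_equal(oral$n_population, 2L)
  expect_equal(oral$pct_population, 50)
  # counts sum to the cohort size within each variable
  for (v in unique(ch$variable)) {
    expect_equal(sum(ch$n_population[ch$variable == v]), 4L)
    expect_equal(sum(ch$pct_population[ch$variable == v]), 100)
  }
  # paired sample adds sample columns; population-only table has none
  smp <- draw_sample(cohort, 2, seed = 1)
  ch2 <- characterize(cohort, smp)
  expect_true(all(c("n_sample", "pct_sample") %in% names(ch2)))
  expect_false("n_sample" %in% names(ch))
})

test_that("published population counts give the published percentages", {
  counts <- dutch_cohort_counts()
  ch <- characteristics_from_counts("route", counts$population$route)
  expect_equal(ch$n_population[ch$category == "oral"], 1046L)
  expect_equal(round(ch$pct_population[ch$category == "oral"], 1), 56.7)
  expect_equal(sum(ch$n_population), 1844L)
})

test_that("chi-square representativeness matches hand computation", {
  counts <- dutch_cohort_counts()
  ch <- characteristics_from_counts("year", counts$population$year,
                                    counts$sample$year)
  res <- representativeness_test(ch, "year")
  # hand-computed: expected 68.0/77.1/82.6/96.3 for observed 58/77/77/112
  expected <- sum(counts$sample$year) *
    counts$population$year / sum(counts$population$year)
  hand <- sum((counts$sample$year - expected)^2 / expected)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$statistic, 4.41, tolerance = 0.01)
  expect_equal(res$df, 3)
  expect_equal(res$n_flagged_categories, 0L)

  # a perfectly proportional sample gives statistic 0, p = 1
  ch0 <- characteristics_from_counts(
    "route", c(oral = 100L, rectal = 60L, ocular = 40L),
    c(oral = 50L, rectal = 30L, ocular = 20L))
  res0 <- representativeness_test(ch0, "route")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # degenerate single-category variable
  ch1 <- characteristics_from_counts("route", c(oral = 10L), c(oral = 5L))
  expect_error(representativeness_test(ch1, "route"), "single category")
})

test_that("a cohort is perfectly representative of itself (property)", {
  g <- generate_cohort(generator_spec(n = 300, seed = 21))
  ch <- characterize(g$cohort, g$cohort)
  for (v in c("year", "route", "atc_class")) {
    res <- representativeness_test(ch, v)
    expect_equal(res$statistic, 0, tolerance = 1e-12)
    expect_equal(res$p_value, 1)
  }
})

test_that("stratified scores use type-7 quartiles per stratum", {
  scored <- tibble::tibble(
    overall = c(8, 4, 8, 12, 36, 36, 54, 72),
    atc_code = c("A01", rep("N05", 3), rep("L01", 4)))
  ss <- stratified_scores(scored, "atc_class")
  expect_equal(ss$median[ss$stratum == "A"], 8)
  expect_equal(ss$q1[ss$stratum == "A"], 8)   # single record: all quartiles
  expect_equal(ss$median[ss$stratum == "N"], 8)
  expect_equal(ss$median[ss$stratum == "L"], 45)  # midpoint of 36,54
  expect_equal(ss$n, c(1L, 4L, 3L))
})

test_that("Kruskal-Wallis and Dunn agree with hand-computed ranks", {
  scored <- tibble::tibble(overall = c(1, 2, 3, 4),
                           route = c("oral", "oral", "rectal", "rectal"))
  res <- compare_strata(scored, "route", p_adjust = "none")
  kw <- res[res$test == "kruskal_wallis", ]
  # ranks 1,2 vs 3,4: H = 12/(4*5) * 2*((1.5-2.5)^2 + (3.5-2.5)^2) = 2.4
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$df, 1)
  dunn <- res[res$test == "dunn", ]
  # z = (1.5 - 3.5) / sqrt((4*5/12) * (1/2 + 1/2)) = -2 / sqrt(5/3)
  expect_equal(dunn$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(dunn$p_value, 2 * pnorm(-abs(dunn$statistic)))

  # identical score groups: omnibus statistic 0
  tied <- tibble::tibble(overall = rep(c(5, 7), 2),
                         route = rep(c("oral", "rectal"), each = 2))
  kw0 <- compare_strata(tied, "route")
  expect_equal(kw0$statistic[kw0$test == "kruskal_wallis"], 0)

  # three strata produce three pairwise Dunn rows
  three <- tibble::tibble(overall = c(1, 2, 3, 4, 5, 6),
                          route = rep(c("oral", "rectal", "ocular"), each = 2))
  res3 <- compare_strata(three, "route")
  expect_equal(sum(res3$test == "dunn"), 3L)
  expect_true(all(res3$adjustment[res3$test == "dunn"] == "bonferroni"))
  expect_error(compare_strata(tibble::tibble(overall = 1:3,
                                             route = rep("oral", 3)),
                              "route"), "at least 2")
})

test_that("Dunn tie correction matches the hand formula on a tied sample", {
  x <- c(1, 2, 2, 3, 3, 3, 5, 6)
  g <- factor(rep(c("a", "b"), each = 4))
  res <- dunn_test(x, g, p_adjust = "none")
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  z_hand <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt((N * (N + 1) / 12 - tc) * (1 / 4 + 1 / 4))
  expect_equal(res$statistic, z_hand)
  # Bonferroni p never below the raw p
  res_b <- dunn_test(c(x, 9, 10), factor(c(as.character(g), "c", "c")),
                     p_adjust = "bonferroni")
  res_n <- dunn_test(c(x, 9, 10), factor(c(as.character(g), "c", "c")),
                     p_adjust = "none")
  expect_true(all(res_b$p_value >= res_n$p_value - 1e-15))
})

test_that("rank tests are invariant under monotone score transforms", {
  g <- generate_cohort(generator_spec(n = 120, seed = 13))
  scored <- suppressMessages(score_cohort(g$cohort, config = g$spec$config))
  res1 <- compare_strata(scored, "route")
  scored2 <- scored
  scored2$overall <- log(scored2$overall + 1) * 10
  res2 <- compare_strata(scored2, "route")
  expect_equal(res1$statistic, res2$statistic)
  expect_equal(res1$p_value, res2$p_value)
})

test_that("rating distribution percentages are consistent", {
  grid <- all_profiles()
  scored <- aggregate_scores(grid[c(1, 243, 1, 1), ])  # 3x all-low, 1x all-high
  d <- rating_distribution(scored)
  alt <- d$elements[d$elements$element == "alternative", ]
  expect_equal(alt$pct[alt$rating == 1], 75)
  expect_equal(alt$pct[alt$rating == 3], 25)
  expect_equal(d$summary$pct[d$summary$share == "high_on_ge1_element"], 25)
  expect_equal(d$summary$pct[d$summary$share == "low_on_all_elements"], 75)
  # per-element percentages sum to 100
  sums <- tapply(d$elements$pct, d$elements$element, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # high-on->=1 always at least high-on->=2
  expect_gte(d$summary$pct[d$summary$share == "high_on_ge1_element"],
             d$summary$pct[d$summary$share == "high_on_ge2_elements"])
})

test_that("yearly trends summarise per start year", {
  g <- generate_cohort(generator_spec(n = 200, seed = 31))
  scored <- suppressMessages(score_cohort(g$cohort, config = g$spec$config))
  tr <- yearly_trends(scored)
  expect_setequal(tr$scores$year, as.character(2012:2015))
  expect_equal(sum(tr$scores$n), nrow(scored))
  expect_true(all(tr$scores$q1 <= tr$scores$median &
                    tr$scores$median <= tr$scores$q3))
  # two identical single-year cohorts give identical medians
  one_year <- scored[format(scored$start_date, "%Y") == "2013", ]
  tr1 <- yearly_trends(one_year)
  expect_equal(nrow(tr1$scores), 1L)
})
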