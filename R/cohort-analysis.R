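# Cohort-level statistics: sample-size calculation, random sampling,
# characterisation tables, representativeness testing, stratified score
# summaries and comparisons, rating distributions and yearly trends.

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Finite-population sample size for a proportion
#'
#' Classical sample-size formula for estimating a proportion: n0 =
#' z^2 p (1 - p) / e^2 with z the two-sided normal quantile for the
#' confidence level, then corrected for a finite population of size N as
#' n = n0 / (1 + (n0 - 1) / N), rounded up. The exact normal quantile is
#' used (1.959964 at 95%, not 1.96). With N = 1844, 95% confidence, a +/-5%
#' margin and p = 0.5 this gives 319.
#'
#' @param population_size Size N of the finite population.
#' @param confidence Confidence level (default 0.95).
#' @param margin Margin of random error e as a proportion (default 0.05).
#' @param proportion Assumed population proportion p (default 0.5, the most
#'   conservative choice).
#' @return Integer required sample size.
#' @export
required_sample_size <- function(population_size, confidence = 0.95,
                                 margin = 0.05, proportion = 0.5) {
  if (population_size < 1) abort("population_size must be at least 1.")
  if (margin <= 0 || margin >= 1) abort("margin must lie strictly in (0, 1).")
  if (proportion <= 0 || proportion >= 1) {
    abort("proportion must lie strictly in (0, 1).")
  }
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must lie strictly in (0, 1).")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * proportion * (1 - proportion) / margin^2
  n <- n0 / (1 + (n0 - 1) / population_size)
  as.integer(ceiling(n))
}

#' Draw a simple random sample from a cohort
#'
#' Sampling is without replacement and reproducible for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param cohort A [shortage_cohort()].
#' @param n Sample size; must not exceed the cohort size.
#' @param seed Integer seed.
#' @return A [shortage_cohort()] of `n` records.
#' @export
draw_sample <- function(cohort, n, seed = 1L) {
  stopifnot(inherits(cohort, "shortage_cohort"))
  total <- nrow(cohort$records)
  if (n > total) {
    abort(paste0("Cannot sample ", n, " records from a cohort of ", total, "."))
  }
  idx <- with_local_seed(seed, sample.int(total, n))
  cohort$records <- cohort$records[idx, , drop = FALSE]
  cohort$provenance <- paste0(cohort$provenance, " (random sample n=", n,
                              ", seed=", seed, ")")
  cohort
}

# derive the stratification variables used throughout the cohort analyses
stratum_values <- function(records, variable) {
  switch(variable,
    year = as.character(as.integer(format(records$start_date, "%Y"))),
    route = records$route,
    atc_class = toupper(substr(records$atc_code, 1, 1)),
    originator = ifelse(records$originator, "originator", "generic"),
    {
      if (!variable %in% names(records)) {
        abort(paste0("Unknown stratum variable: ", variable))
      }
      as.character(records[[variable]])
    })
}

#' Characterise a cohort (and optionally a paired sample)
#'
#' Counts and percentages per category for the standard descriptive
#' variables: year the shortage started, route of administration, ATC
#' anatomical main group and originator/generic status. Percentages are
#' computed over the number of records in the respective group.
#'
#' @param cohort A [shortage_cohort()] (the population).
#' @param sample Optional [shortage_cohort()] drawn from the population.
#' @param variables Character vector of variables to tabulate.
#' @return A tibble of class `cohort_characteristics` with columns
#'   `variable`, `category`, `n_population`, `pct_population` and, when a
#'   sample is given, `n_sample`, `pct_sample`.
#' @export
characterize <- function(cohort, sample = NULL,
                         variables = c("year", "route", "atc_class",
                                       "originator")) {
  stopifnot(inherits(cohort, "shortage_cohort"))
  tab_one <- function(records, variable) {
    v <- stratum_values(records, variable)
    counts <- table(v)
    tibble::tibble(variable = variable, category = names(counts),
                   n = as.integer(counts),
                   pct = 100 * as.integer(counts) / length(v))
  }
  pop <- dplyr::bind_rows(lapply(variables, tab_one,
                                 records = cohort$records))
  pop <- dplyr::rename(pop, n_population = n, pct_population = pct)
  if (!is.null(sample)) {
    stopifnot(inherits(sample, "shortage_cohort"))
    smp <- dplyr::bind_rows(lapply(variables, tab_one,
                                   records = sample$records))
    smp <- dplyr::rename(smp, n_sample = n, pct_sample = pct)
    pop <- dplyr::left_join(pop, smp, by = c("variable", "category"))
    pop$n_sample[is.na(pop$n_sample)] <- 0L
    pop$pct_sample[is.na(pop$pct_sample)] <- 0
  }
  class(pop) <- c("cohort_characteristics", class(pop))
  pop
}

new_test_result <- function(test, statistic, df, p_value,
                            adjustment = "none", ...) {
  tibble::tibble(test = test, statistic = statistic, df = df,
                 p_value = p_value, adjustment = adjustment, ...)
}

#' Chi-square representativeness test of a sample against its population
#'
#' Goodness-of-fit of the sample's category counts against the population
#' proportions (the sample is a subset of the population, so a
#' goodness-of-fit formulation is used). Categories with expected count
#' below 5 are flagged; a variable with a single category is degenerate
#' (zero degrees of freedom) and raises an error.
#'
#' @param characteristics A [characterize()] table that includes sample
#'   counts, or the population counts when `sample_counts` is given.
#' @param variable Which variable to test (e.g. `"year"`).
#' @param sample_counts Optional integer vector of sample counts matching
#'   the population categories, for use with bare count tables.
#' @return A one-row tibble: `test`, `variable`, `statistic`, `df`,
#'   `p_value`, `adjustment`, `n_flagged_categories` (expected < 5).
#' @export
representativeness_test <- function(characteristics, variable,
                                    sample_counts = NULL) {
  tab <- characteristics[characteristics$variable == variable, , drop = FALSE]
  if (nrow(tab) == 0) abort(paste0("No categories for variable ", variable))
  if (nrow(tab) < 2) {
    abort(paste0("Variable '", variable,
                 "' has a single category; a chi-square test is undefined."))
  }
  observed <- sample_counts %||% tab$n_sample
  if (is.null(observed)) {
    abort("Sample counts required: characterize() with a sample, or sample_counts.")
  }
  p <- tab$n_population / sum(tab$n_population)
  if (any(p == 0)) {
    abort("Zero-count population category; pool categories before testing.")
  }
  expected <- sum(observed) * p
  fit <- suppressWarnings(chisq.test(observed, p = p))
  new_test_result(
    test = "chi_square_goodness_of_fit",
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = unname(fit$p.value), variable = variable,
    n_flagged_categories = sum(expected < 5))
}

#' Median and quartiles of overall scores per stratum
#'
#' Quartiles use linear interpolation on the sorted sample (type 7), the
#' same estimator as the cohort-relative cost thresholds.
#'
#' @param scored A scored table (see [aggregate_scores()]) that still
#'   carries the registry columns.
#' @param by Stratum variable: `"year"`, `"route"`, `"atc_class"`,
#'   `"originator"` or any column name.
#' @return A tibble with `stratum`, `n`, `median`, `q1`, `q3` per non-empty
#'   stratum.
#' @export
stratified_scores <- function(scored, by) {
  scored <- tibble::as_tibble(scored)
  if (!"overall" %in% names(scored)) {
    abort("Scores missing: run aggregate_scores() first.")
  }
  g <- stratum_values(scored, by)
  keep <- !is.na(g)
  if (any(!keep)) {
    warn(paste0("stratified_scores: dropped ", sum(!keep),
                " record(s) with missing ", by, "."))
  }
  split_scores <- split(scored$overall[keep], g[keep])
  dplyr::bind_rows(lapply(names(split_scores), function(s) {
    x <- split_scores[[s]]
    q <- unname(quantile(x, probs = c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(stratum = s, n = length(x), median = q[2],
                   q1 = q[1], q3 = q[3])
  }))
}

#' Compare overall scores across strata
#'
#' Omnibus Kruskal-Wallis rank test over the strata, followed by pairwise
#' Dunn tests with the configured multiplicity adjustment. Both are
#' rank-based, so results are invariant under monotone transformations of
#' the scores.
#'
#' @param scored A scored table (see [stratified_scores()]).
#' @param by Stratum variable.
#' @param p_adjust Adjustment for the pairwise Dunn p-values:
#'   `"bonferroni"` (default), `"holm"` or `"none"`; the label is recorded
#'   in the result.
#' @return A tibble of test results: one `kruskal_wallis` row (statistic,
#'   df, p_value) and one `dunn` row per stratum pair (z statistic,
#'   adjusted p_value, `stratum_1`, `stratum_2`).
#' @export
compare_strata <- function(scored, by,
                           p_adjust = c("bonferroni", "holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  scored <- tibble::as_tibble(scored)
  g <- stratum_values(scored, by)
  keep <- !is.na(g)
  x <- scored$overall[keep]
  g <- factor(g[keep])
  if (nlevels(g) < 2) {
    abort("compare_strata needs at least 2 non-empty strata.")
  }
  kw <- kruskal.test(x, g)
  omnibus <- new_test_result(
    test = "kruskal_wallis", statistic = unname(kw$statistic),
    df = unname(kw$parameter), p_value = unname(kw$p.value),
    variable = by, stratum_1 = NA_character_, stratum_2 = NA_character_)
  pairwise <- dunn_test(x, g, p_adjust = p_adjust)
  pairwise$variable <- by
  dplyr::bind_rows(omnibus, pairwise)
}

#' Dunn's post-hoc test for pairwise stratum comparisons
#'
#' Pairwise z tests on mean ranks from the pooled ranking, with the usual
#' tie correction: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i +
#' 1/n_j)) where T = sum(t^3 - t) / (12 (N - 1)) over tie groups. Two-sided
#' p-values are adjusted for the number of pairs.
#'
#' @param x Numeric response (e.g. overall scores).
#' @param g Grouping factor.
#' @param p_adjust `"bonferroni"`, `"holm"` or `"none"`.
#' @return A tibble with one row per group pair: `test`, `statistic` (z),
#'   `df` (NA; z test), `p_value` (adjusted), `adjustment`, `stratum_1`,
#'   `stratum_2`.
#' @export
dunn_test <- function(x, g, p_adjust = c("bonferroni", "holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  g <- droplevels(factor(g))
  if (nlevels(g) < 2) abort("dunn_test needs at least 2 groups.")
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- pmin(1, p.adjust(p_raw, method = p_adjust))
  new_test_result(test = "dunn", statistic = z, df = NA_real_,
                  p_value = p_adj, adjustment = p_adjust,
                  stratum_1 = pairs[1, ], stratum_2 = pairs[2, ])
}

#' Distribution of element ratings and ECHO outcomes over a scored cohort
#'
#' For each of the five elements and each ECHO outcome, the percentage of
#' records at each rating, plus the summary shares used to describe a
#' cohort: high on at least one element, high on two or more (unforgiving),
#' low on all elements, high on direct impact (alternative product or
#' disease), and the additional share high on indirect impact only (costs,
#' susceptibility or number of patients, without a high direct rating).
#'
#' @param scored A scored table (see [aggregate_scores()]).
#' @return A list of class `rating_distribution` with tibbles `elements`
#'   (element, rating, n, pct), `echo` (outcome, rating, n, pct) and
#'   `summary` (share, pct).
#' @export
rating_distribution <- function(scored) {
  scored <- tibble::as_tibble(scored)
  n_total <- nrow(scored)
  elements <- c(alternative = "rating_alternative",
                disease = "rating_disease",
                susceptibility = "rating_susceptibility",
                costs = "rating_costs",
                n_patients = "rating_n_patients")
  tab_ratings <- function(cols, label_name) {
    dplyr::bind_rows(lapply(names(cols), function(el) {
      counts <- table(factor(scored[[cols[[el]]]], levels = 1:3))
      out <- tibble::tibble(rating = 1:3, n = as.integer(counts),
                            pct = if (n_total > 0) {
                              100 * as.integer(counts) / n_total
                            } else rep(NA_real_, 3))
      out[[label_name]] <- el
      out[, c(label_name, "rating", "n", "pct")]
    }))
  }
  echo_cols <- c(economic = "echo_economic", clinical = "echo_clinical",
                 humanistic = "echo_humanistic")
  have_echo <- all(echo_cols %in% names(scored))
  summary <- tibble::tibble(
    share = c("high_on_ge1_element", "high_on_ge2_elements",
              "low_on_all_elements", "direct_high", "indirect_high_only"),
    pct = if (n_total > 0) 100 * c(
      mean(scored$n_high_elements >= 1),
      mean(scored$n_high_elements >= 2),
      mean(scored$rating_alternative == 1L & scored$rating_disease == 1L &
             scored$rating_susceptibility == 1L & scored$rating_costs == 1L &
             scored$rating_n_patients == 1L),
      mean(scored$direct_high),
      mean(scored$indirect_high & !scored$direct_high)
    ) else rep(NA_real_, 5))
  structure(list(
    elements = tab_ratings(elements, "element"),
    echo = if (have_echo) tab_ratings(echo_cols, "outcome") else NULL,
    summary = summary,
    n = n_total
  ), class = "rating_distribution")
}

#' @export
print.rating_distribution <- function(x, ...) {
  cat("<rating_distribution> n =", x$n, "\n")
  print(tidyr::pivot_wider(x$elements, id_cols = "element",
                           names_from = "rating", values_from = "pct",
                           names_prefix = "pct_"))
  if (!is.null(x$echo)) {
    print(tidyr::pivot_wider(x$echo, id_cols = "outcome",
                             names_from = "rating", values_from = "pct",
                             names_prefix = "pct_"))
  }
  print(x$summary)
  invisible(x)
}

#' Yearly trends in scores and ratings
#'
#' Per calendar year in which the shortage started: the overall-score
#' summary (n, median, quartiles) and the element rating distribution.
#'
#' @param scored A scored table that still carries `start_date`.
#' @return A list with tibbles `scores` (one row per year) and `ratings`
#'   (long: year, element, rating, n, pct).
#' @export
yearly_trends <- function(scored) {
  scored <- tibble::as_tibble(scored)
  years <- stratum_values(scored, "year")
  scores <- stratified_scores(scored, "year")
  scores <- dplyr::rename(scores, year = stratum)
  ratings <- dplyr::bind_rows(lapply(sort(unique(years)), function(y) {
    d <- rating_distribution(scored[years == y, , drop = FALSE])
    out <- d$elements
    out$year <- y
    out[, c("year", "element", "rating", "n", "pct")]
  }))
  list(scores = scores, ratings = ratings)
}

#' Build a characteristics table from published counts
#'
#' Constructs the same table as [characterize()] from category counts
#' rather than record-level data, for working with published cohort
#' descriptions.
#'
#' @param variable Variable name the counts describe.
#' @param counts Named integer vector of category counts.
#' @param sample_counts Optional named integer vector of sample counts over
#'   the same categories.
#' @return A `cohort_characteristics` tibble.
#' @export
characteristics_from_counts <- function(variable, counts,
                                        sample_counts = NULL) {
  out <- tibble::tibble(
    variable = variable, category = names(counts),
    n_population = as.integer(counts),
    pct_population = 100 * as.integer(counts) / sum(counts))
  if (!is.null(sample_counts)) {
    stopifnot(setequal(names(sample_counts), names(counts)))
    sc <- sample_counts[names(counts)]
    out$n_sample <- as.integer(sc)
    out$pct_sample <- 100 * as.integer(sc) / sum(sc)
  }
  class(out) <- c("cohort_characteristics", class(out))
  out
}

#' Published characteristics of the Dutch 2012-2015 shortage cohort
#'
#' Category counts for the 1844 shortages reported in the Netherlands
#' between 2012 and 2015, and for the representative sample of 324 rated
#' shortages: year the shortage started, route of administration, ATC
#' anatomical main group, and originator/generic status. These counts also
#' parameterise the default marginals of [generator_spec()].
#'
#' @return A named list with elements `population` and `sample`, each a
#'   named list of integer count vectors per variable.
#' @export
dutch_cohort_counts <- function() {
  list(
    population = list(
      year = c(`2012` = 387L, `2013` = 439L, `2014` = 470L, `2015` = 548L),
      route = c(oral = 1046L, parenteral = 554L, nasal_inhalation = 42L,
                cutaneous = 77L, rectal = 25L, ocular = 65L, other = 35L),
      atc_class = c(A = 168L, B = 91L, C = 240L, D = 83L, G = 77L, H = 84L,
                    J = 311L, L = 148L, M = 85L, N = 333L, P = 4L, R = 88L,
                    S = 78L, V = 54L),
      originator = c(originator = 1011L, generic = 833L)
    ),
    sample = list(
      year = c(`2012` = 58L, `2013` = 77L, `2014` = 77L, `2015` = 112L),
      route = c(oral = 168L, parenteral = 104L, nasal_inhalation = 8L,
                cutaneous = 13L, rectal = 8L, ocular = 16L, other = 7L),
      atc_class = c(A = 27L, B = 17L, C = 38L, D = 15L, G = 13L, H = 11L,
                    J = 59L, L = 26L, M = 15L, N = 56L, P = 3L, R = 12L,
                    S = 17L, V = 15L),
      originator = c(originator = 176L, generic = 148L)
    )
  )
}
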