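# Seeded generator of synthetic shortage cohorts. Marginal structure (year,
# route, ATC main group, originator share) defaults to the Dutch 2012-2015
# cohort; element-rating distributions default to the reported shares where
# published, with the remaining cells chosen as plausible values. Raw record
# attributes are constructed so that the element raters reproduce the sampled
# ground-truth ratings exactly, which makes rating recovery a machine-checkable
# contract of the pipeline.

default_marginals <- function() {
  list(
    year = c(`2012` = 387, `2013` = 439, `2014` = 470, `2015` = 548) / 1844,
    route = c(oral = 1046, parenteral = 554, nasal_inhalation = 42,
              cutaneous = 77, rectal = 25, ocular = 65, other = 35) / 1844,
    atc_class = c(A = 168, B = 91, C = 240, D = 83, G = 77, H = 84, J = 311,
                  L = 148, M = 85, N = 333, P = 4, R = 88, S = 78,
                  V = 54) / 1844,
    originator = 1011 / 1844
  )
}

default_rating_probs <- function() {
  list(
    # published shares: alternative high 1% / moderate 60%; disease high 29%;
    # susceptibility low 79%. Unpublished cells split plausibly (see vignette).
    alternative = c(0.39, 0.60, 0.01),
    disease = c(0.25, 0.46, 0.29),
    susceptibility = c(0.79, 0.18, 0.03),
    n_patients = c(0.30, 0.60, 0.10)
  )
}

#' Specification of a synthetic shortage cohort
#'
#' Collects every knob of the generator: cohort size, seed, categorical
#' marginals, per-element rating probabilities, the cost-ratio distribution
#' and the structural shares. The cost element is not target-sampled:
#' because its rating is cohort-relative (quartiles of the cohort's own
#' ratio distribution), cost ratings emerge from the log-normal ratio draw
#' and the missing-price share. With the default missing share of 0.2 the
#' expected share of records rated high on costs is 0.8 x 25% = 20%.
#'
#' @param n Cohort size (default 324, the size of a representative sample of
#'   the 1844-shortage population).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param marginals Named list of category probabilities for `year`,
#'   `route`, `atc_class`, and the `originator` share.
#' @param rating_probs Named list of length-3 probability vectors over
#'   ratings 1/2/3 for `alternative`, `disease`, `susceptibility`,
#'   `n_patients`.
#' @param cost_ratio_meanlog,cost_ratio_sdlog Log-normal parameters of the
#'   alternative/original cost ratio in percent (default: median 100%,
#'   sdlog 0.6).
#' @param missing_price_share Share of records with missing prices (beyond
#'   those without any alternative).
#' @param hospital_share Share of records realised as hospital products
#'   without usage statistics (must fit inside the moderate n_patients
#'   probability).
#' @param orphan_share Share of records with an orphan indication (must fit
#'   inside the low n_patients probability).
#' @param ongoing_share Share of episodes still ongoing (no end date).
#' @param config The [rater_config()] the construction targets; rating
#'   recovery is guaranteed only under this configuration.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n = 324, seed = 1L,
                           marginals = default_marginals(),
                           rating_probs = default_rating_probs(),
                           cost_ratio_meanlog = log(100),
                           cost_ratio_sdlog = 0.6,
                           missing_price_share = 0.2,
                           hospital_share = 0.15,
                           orphan_share = 0.05,
                           ongoing_share = 0.03,
                           config = rater_config()) {
  if (n < 0) abort("n must be non-negative.")
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " probabilities must be non-negative and sum to 1."))
    }
  }
  for (v in c("year", "route", "atc_class")) {
    check_probs(marginals[[v]], paste0("marginals$", v))
  }
  if (marginals$originator < 0 || marginals$originator > 1) {
    abort("marginals$originator must be a proportion.")
  }
  for (el in names(rating_probs)) check_probs(rating_probs[[el]], el)
  shares <- c(missing_price_share, hospital_share, orphan_share,
              ongoing_share)
  if (any(shares < 0 | shares > 1)) {
    abort("All shares must be proportions in [0, 1].")
  }
  if (orphan_share > rating_probs$n_patients[1] + 1e-12) {
    abort("orphan_share cannot exceed the probability of a low n_patients rating.")
  }
  if (hospital_share > rating_probs$n_patients[2] + 1e-12) {
    abort("hospital_share cannot exceed the probability of a moderate n_patients rating.")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed), marginals = marginals,
    rating_probs = rating_probs, cost_ratio_meanlog = cost_ratio_meanlog,
    cost_ratio_sdlog = cost_ratio_sdlog,
    missing_price_share = missing_price_share,
    hospital_share = hospital_share, orphan_share = orphan_share,
    ongoing_share = ongoing_share, config = config
  ), class = "generator_spec")
}

sample_rating <- function(n, probs) {
  if (n == 0) return(integer(0))
  sample.int(3L, n, replace = TRUE, prob = probs)
}

# ages realising a target vulnerability rating under the config's bounds
ages_for_vulnerability <- function(v, config) {
  child_max <- config$child_age_max
  elderly_min <- config$elderly_age_min
  n <- length(v)
  age_min <- integer(n)
  age_max <- integer(n)
  side <- runif(n) < 0.5
  for (i in seq_len(n)) {
    if (v[i] == 1L) {
      age_min[i] <- sample(child_max:(child_max + 22), 1)
      age_max[i] <- sample((child_max + 27):elderly_min, 1)
    } else if (v[i] == 2L) {
      if (side[i]) { # includes children among adults
        age_min[i] <- sample(0:(child_max - 8), 1)
        age_max[i] <- sample((child_max + 12):(elderly_min - 1), 1)
      } else {       # includes the elderly among adults
        age_min[i] <- sample(child_max:(elderly_min - 5), 1)
        age_max[i] <- sample((elderly_min + 5):95, 1)
      }
    } else {
      if (side[i]) { # confined to children
        age_min[i] <- sample(0:5, 1)
        age_max[i] <- sample(6:(child_max - 1), 1)
      } else {       # confined to the elderly
        age_min[i] <- sample((elderly_min + 1):(elderly_min + 15), 1)
        age_max[i] <- sample((elderly_min + 16):99, 1)
      }
    }
  }
  list(age_min = age_min, age_max = age_max)
}

# severity field realising a target disease rating (mix of enumerants and
# numeric disability weights inside the config's cutpoint bands)
severity_for_rating <- function(d, config) {
  n <- length(d)
  use_weight <- runif(n) < 0.3
  out <- character(n)
  lo <- config$disability_low_max
  hi <- config$disability_high_min
  for (i in seq_len(n)) {
    if (d[i] == 1L) {
      out[i] <- if (use_weight[i]) {
        sprintf("%.3f", runif(1, 0.011, lo - 0.005))
      } else "mild"
    } else if (d[i] == 2L) {
      out[i] <- if (use_weight[i]) {
        sprintf("%.3f", runif(1, lo + 0.005, hi - 0.005))
      } else if (runif(1) < 0.25) "multi_class" else "moderate"
    } else {
      out[i] <- if (use_weight[i]) {
        sprintf("%.3f", runif(1, hi + 0.005, 0.95))
      } else "severe"
    }
  }
  out
}

log_uniform_count <- function(n, lower, upper) {
  pmin(pmax(round(exp(runif(n, log(lower), log(upper)))), lower), upper)
}

#' Generate a synthetic shortage cohort with ground-truth ratings
#'
#' Samples ground-truth element ratings from the spec's rating
#' probabilities, then constructs raw record attributes that reproduce those
#' ratings when passed through the element raters under the spec's
#' configuration (a record destined for disease rating 3 gets a severe
#' indication, a child-only age range realises a high vulnerability aspect,
#' and so on). Cost ratings are derived, not sampled: ratios are drawn
#' log-normal and the ground-truth cost aspect is obtained by applying the
#' cohort-relative quartile rule to the generated ratio sample, so boundary
#' records are self-consistent by construction. Attributes are sampled
#' independently across variables.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `synthetic_cohort`: a list with `cohort` (a
#'   [shortage_cohort()]), `truth` (tibble of ground-truth element and
#'   aspect ratings plus the ground-truth overall score, keyed by
#'   `shortage_id`), `thresholds` (the cohort-relative `cost_thresholds`, or
#'   NULL when all prices are missing) and `spec`.
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n
  if (n == 0) {
    empty <- tibble::as_tibble(
      setNames(rep(list(character(0)), length(cohort_columns)),
               cohort_columns))
    empty <- coerce_record_types(empty)
    return(structure(list(
      cohort = structure(list(records = empty,
                              provenance = "synthetic (empty)"),
                         class = "shortage_cohort"),
      truth = tibble::tibble(shortage_id = character(0)),
      thresholds = NULL, spec = spec), class = "synthetic_cohort"))
  }
  config <- spec$config
  with_local_seed(spec$seed, {
    shortage_id <- sprintf("SYN%05d", seq_len(n))
    year <- sample(names(spec$marginals$year), n, replace = TRUE,
                   prob = spec$marginals$year)
    start_date <- as.Date(paste0(year, "-01-01")) +
      sample.int(365, n, replace = TRUE) - 1L
    duration <- 14L + as.integer(round(rexp(n, rate = 1 / 46)))
    end_date <- start_date + duration - 1L
    end_date[runif(n) < spec$ongoing_share] <- NA
    route <- sample(names(spec$marginals$route), n, replace = TRUE,
                    prob = spec$marginals$route)
    atc_class <- sample(names(spec$marginals$atc_class), n, replace = TRUE,
                        prob = spec$marginals$atc_class)
    atc_code <- paste0(atc_class,
                       sprintf("%02d", sample.int(16, n, replace = TRUE)),
                       sample(LETTERS, n, replace = TRUE),
                       sample(LETTERS, n, replace = TRUE),
                       sprintf("%02d", sample.int(99, n, replace = TRUE)))
    originator <- runif(n) < spec$marginals$originator

    # --- alternative product -------------------------------------------------
    t_alt <- sample_rating(n, spec$rating_probs$alternative)
    ladder <- config$solution_ladder
    pick_solution <- function(r) {
      candidates <- names(ladder)[ladder == r]
      if (length(candidates) == 1) candidates else {
        sample(candidates, 1, prob = c(0.6, rep(0.4 / (length(candidates) - 1),
                                                length(candidates) - 1)))
      }
    }
    solution_category <- vapply(t_alt, pick_solution, character(1))

    # --- disease -------------------------------------------------------------
    t_dis <- sample_rating(n, spec$rating_probs$disease)
    disease_severity <- severity_for_rating(t_dis, config)

    # --- susceptibility: split the target over the two aspects ---------------
    t_sus <- sample_rating(n, spec$rating_probs$susceptibility)
    carrier <- sample(c("vulnerability", "trust", "both"), n, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
    t_vuln <- ifelse(t_sus == 1L, 1L,
                     ifelse(carrier == "trust",
                            vapply(t_sus, function(s) sample.int(s, 1),
                                   integer(1)),
                            t_sus))
    t_trust <- ifelse(t_sus == 1L, 1L,
                      ifelse(carrier == "vulnerability",
                             vapply(t_sus, function(s) sample.int(s, 1),
                                    integer(1)),
                             t_sus))
    ages <- ages_for_vulnerability(as.integer(t_vuln), config)
    patient_contact_notes <- t_trust == 2L |
      (t_trust == 3L & runif(n) < 0.3)
    media_attention <- t_trust == 3L & runif(n) < 0.7
    patient_forum_reports <- t_trust == 3L & runif(n) < 0.5
    fix <- t_trust == 3L & !media_attention & !patient_forum_reports
    media_attention[fix] <- TRUE

    # --- number of patients --------------------------------------------------
    t_np <- sample_rating(n, spec$rating_probs$n_patients)
    p_np <- spec$rating_probs$n_patients
    orphan_indication <- t_np == 1L &
      runif(n) < min(1, spec$orphan_share / max(p_np[1], 1e-12))
    hospital_product <- t_np == 2L &
      runif(n) < min(1, spec$hospital_share / max(p_np[2], 1e-12))
    users_prior_year <- rep(NA_real_, n)
    low_max <- config$n_patients_low_max
    high_min <- config$n_patients_high_min
    i1 <- t_np == 1L & !(orphan_indication & runif(n) < 0.5)
    users_prior_year[i1] <- log_uniform_count(sum(i1), 5, low_max)
    i2 <- t_np == 2L & !hospital_product
    users_prior_year[i2] <- log_uniform_count(sum(i2), low_max + 1,
                                              high_min - 1)
    i3 <- t_np == 3L
    users_prior_year[i3] <- log_uniform_count(sum(i3), high_min,
                                              20 * high_min)

    # --- costs: ratios drawn, ratings derived cohort-relatively --------------
    missing_price <- t_alt == 3L | runif(n) < spec$missing_price_share
    price_original <- pmax(round(rlnorm(n, log(50), 0.8), 2), 0.05)
    ratio_drawn <- rlnorm(n, spec$cost_ratio_meanlog, spec$cost_ratio_sdlog)
    price_alternative <- pmax(round(price_original * ratio_drawn / 100, 2),
                              0.01)
    price_original[missing_price] <- NA_real_
    price_alternative[missing_price] <- NA_real_
    if (sum(!missing_price) < 4) {
      # too few ratios for cohort-relative thresholds: omit all prices
      price_original[] <- NA_real_
      price_alternative[] <- NA_real_
    }
    ratio_real <- ifelse(is.na(price_original) | is.na(price_alternative),
                         NA_real_, 100 * price_alternative / price_original)
    thresholds <- if (sum(!is.na(ratio_real)) >= 4) {
      compute_cost_thresholds(ratio_real, config)
    } else NULL
    t_medicine <- if (is.null(thresholds)) {
      rep(NA_integer_, n)
    } else {
      ifelse(is.na(ratio_real), NA_integer_,
             ifelse(ratio_real > thresholds$q3, 3L,
                    ifelse(ratio_real < thresholds$q1, 1L, 2L)))
    }
    t_costs <- as.integer(pmax(t_medicine, t_alt, na.rm = TRUE))

    records <- tibble::tibble(
      shortage_id = shortage_id,
      product_name = paste0("product_", shortage_id),
      atc_code = atc_code, route = route, originator = originator,
      start_date = start_date, end_date = end_date,
      solution_category = solution_category,
      disease_severity = disease_severity,
      age_min = as.numeric(ages$age_min), age_max = as.numeric(ages$age_max),
      patient_contact_notes = patient_contact_notes,
      media_attention = media_attention,
      patient_forum_reports = patient_forum_reports,
      price_original = price_original,
      price_alternative = price_alternative,
      users_prior_year = users_prior_year,
      hospital_product = hospital_product,
      orphan_indication = orphan_indication
    )
    truth <- tibble::tibble(
      shortage_id = shortage_id,
      truth_alternative = as.integer(t_alt),
      truth_disease = as.integer(t_dis),
      truth_vulnerability = as.integer(t_vuln),
      truth_trust = as.integer(t_trust),
      truth_susceptibility = as.integer(t_sus),
      truth_medicine_cost = as.integer(t_medicine),
      truth_personnel_cost = as.integer(t_alt),
      truth_costs = t_costs,
      truth_n_patients = as.integer(t_np),
      truth_overall = as.integer(t_alt * t_dis * t_sus * t_costs * t_np)
    )
    structure(list(
      cohort = shortage_cohort(records, provenance = paste0(
        "synthetic cohort (n=", n, ", seed=", spec$seed, ")")),
      truth = truth, thresholds = thresholds, spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$cohort$records),
      "seed =", x$spec$seed, "\n")
  invisible(x)
}

#' Check that the raters recover the generator's ground truth
#'
#' Rates every generated record with [rate_cohort()] under the spec's
#' configuration and reports the per-element exact-agreement rate with the
#' stored ground truth, plus agreement of the overall multiplicative score.
#' Because the generator constructs attributes to invert the raters and the
#' cost thresholds are recomputed from the same cohort, the contract is
#' 100% agreement on every element when generator and rater share a
#' configuration. Records whose cost ratio falls exactly on a quartile
#' boundary are counted in `n_boundary_ratios` (they rate moderate on the
#' medicine-cost aspect on both sides, so they cannot break agreement).
#'
#' @param generated A `synthetic_cohort` from [generate_cohort()].
#' @param config Rater configuration; defaults to the generator's own.
#' @return A tibble with one row per element (and one for the overall
#'   score): `element`, `n`, `n_agree`, `agreement` (proportion). The
#'   boundary-ratio count is attached as attribute `n_boundary_ratios`.
#' @export
recover_ratings_check <- function(generated, config = generated$spec$config) {
  stopifnot(inherits(generated, "synthetic_cohort"))
  n <- nrow(generated$cohort$records)
  if (n == 0) {
    out <- tibble::tibble(element = character(0), n = integer(0),
                          n_agree = integer(0), agreement = numeric(0))
    attr(out, "n_boundary_ratios") <- 0L
    return(out)
  }
  thresholds <- generated$thresholds %||% cost_thresholds(100, 100)
  scored <- rate_cohort(generated$cohort, config = config,
                        thresholds = if (is.null(generated$thresholds)) {
                          thresholds
                        } else NULL)
  merged <- dplyr::inner_join(scored, generated$truth, by = "shortage_id")
  cmp <- function(a, b) sum(a == b | (is.na(a) & is.na(b)))
  rows <- list(
    c("alternative", "rating_alternative", "truth_alternative"),
    c("disease", "rating_disease", "truth_disease"),
    c("susceptibility", "rating_susceptibility", "truth_susceptibility"),
    c("costs", "rating_costs", "truth_costs"),
    c("n_patients", "rating_n_patients", "truth_n_patients"))
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    agree <- cmp(merged[[r[2]]], merged[[r[3]]])
    tibble::tibble(element = r[1], n = n, n_agree = agree,
                   agreement = agree / n)
  }))
  overall <- merged$rating_alternative * merged$rating_disease *
    merged$rating_susceptibility * merged$rating_costs *
    merged$rating_n_patients
  agree_overall <- cmp(overall, merged$truth_overall)
  out <- dplyr::bind_rows(out, tibble::tibble(
    element = "overall_score", n = n, n_agree = agree_overall,
    agreement = agree_overall / n))
  th <- generated$thresholds
  attr(out, "n_boundary_ratios") <- if (is.null(th)) 0L else {
    sum(merged$cost_ratio %in% c(th$q1, th$q3), na.rm = TRUE)
  }
  out
}

#' Write a generator spec to YAML
#' @param spec A [generator_spec()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_generator_spec <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  x <- unclass(spec)
  x$marginals <- lapply(x$marginals, function(m) {
    if (length(m) > 1) as.list(m) else m
  })
  x$rating_probs <- lapply(x$rating_probs, as.list)
  cfg <- unclass(x$config)
  cfg$solution_ladder <- as.list(cfg$solution_ladder)
  x$config <- cfg
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a generator spec from YAML
#' @param path Path to a YAML file as written by [write_generator_spec()].
#' @return A [generator_spec()].
#' @export
read_generator_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$marginals)) {
    x$marginals <- lapply(x$marginals, function(m) {
      if (is.list(m)) unlist(m) else m
    })
  }
  if (!is.null(x$rating_probs)) {
    x$rating_probs <- lapply(x$rating_probs, unlist)
  }
  if (!is.null(x$config)) {
    x$config$solution_ladder <- unlist(x$config$solution_ladder)
    x$config <- do.call(rater_config, x$config)
  }
  do.call(generator_spec, x)
}
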