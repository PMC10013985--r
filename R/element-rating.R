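# Raters for the five elements that drive the patient impact of a shortage:
# alternative product, disease, susceptibility, costs, number of patients.
# Each element is rated 1 (low), 2 (moderate) or 3 (high); an element made of
# several aspects takes the highest aspect rating as its overall rating.

assert_rating <- function(x, what = "rating") {
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 1:3)
  if (any(bad)) {
    abort(paste0(what, " must be 1 (low), 2 (moderate) or 3 (high); got ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

#' Rate the alternative-product element
#'
#' The proposed solution at the start of the shortage determines how
#' disruptive the switch is for patients. The default ladder rates generic
#' substitution (same active substance and route) low, therapeutic
#' substitution and unlicensed products (pharmacy preparations, imports)
#' moderate, and absence of a suitable therapy high; the mapping is
#' configurable through `config$solution_ladder`.
#'
#' @param solution_category Character vector of solution categories (see
#'   [shortage_vocab]).
#' @param config A [rater_config()].
#' @return Integer ratings in `{1, 2, 3}`.
#' @export
rate_alternative_product <- function(solution_category, config = rater_config()) {
  unknown <- !is.na(solution_category) &
    !(solution_category %in% names(config$solution_ladder))
  if (any(unknown)) {
    abort(paste0("Unknown solution_category: ",
                 paste(unique(solution_category[unknown]), collapse = ", "),
                 ". Allowed: ",
                 paste(names(config$solution_ladder), collapse = ", ")))
  }
  unname(config$solution_ladder[solution_category])
}

#' Rate the disease element
#'
#' Severity of the underlying disease, graded through WHO disability weights
#' or a severity enumerant. Enumerants map directly (mild = 1, moderate = 2,
#' severe = 3); a disease classified by WHO at several levels depending on
#' progression (`multi_class`) is regarded as moderate. Numeric disability
#' weights in \[0, 1\] are cut at `config$disability_low_max` (at or below:
#' low) and `config$disability_high_min` (above: high).
#'
#' @param disease_severity Character vector of enumerants or numbers-as-text,
#'   or a numeric vector of disability weights.
#' @param config A [rater_config()].
#' @return Integer ratings in `{1, 2, 3}`.
#' @export
rate_disease <- function(disease_severity, config = rater_config()) {
  sev <- as.character(disease_severity)
  out <- rep(NA_integer_, length(sev))
  out[sev == "mild"] <- 1L
  out[sev %in% c("moderate", "multi_class")] <- 2L
  out[sev == "severe"] <- 3L
  numeric_idx <- which(is.na(out) & !is.na(sev))
  if (length(numeric_idx) > 0) {
    w <- suppressWarnings(as.numeric(sev[numeric_idx]))
    if (anyNA(w)) {
      abort(paste0("Unknown disease_severity: ",
                   paste(unique(sev[numeric_idx][is.na(w)]), collapse = ", ")))
    }
    if (any(w < 0 | w > 1)) {
      abort("Disability weights must lie in [0, 1].")
    }
    out[numeric_idx] <- ifelse(w <= config$disability_low_max, 1L,
                               ifelse(w > config$disability_high_min, 3L, 2L))
  }
  out
}

#' Rate the susceptibility element
#'
#' Susceptibility has two aspects. Vulnerability reflects the age range of
#' the treated population (from the patient leaflet): a population confined
#' to children or to the elderly rates high, one including them alongside
#' adults rates moderate, adults only rates low. Trust in the alternative
#' therapy is graded from surveillance signals: media attention or reports on
#' patient fora rate high, notes on patient contact alone rate moderate, no
#' signals rate low. The element is the maximum of the two aspects.
#'
#' @param age_min,age_max Age range of the treated population in years.
#' @param patient_contact_notes,media_attention,patient_forum_reports Logical
#'   trust-signal flags.
#' @param config A [rater_config()].
#' @return A tibble with integer columns `vulnerability`, `trust` and
#'   `susceptibility` (the element rating).
#' @export
rate_susceptibility <- function(age_min, age_max,
                                patient_contact_notes = FALSE,
                                media_attention = FALSE,
                                patient_forum_reports = FALSE,
                                config = rater_config()) {
  if (any(!is.na(age_min) & !is.na(age_max) & age_min > age_max)) {
    abort("age_min must not exceed age_max.")
  }
  entirely_child <- !is.na(age_max) & age_max <= config$child_age_max
  entirely_elderly <- !is.na(age_min) & age_min >= config$elderly_age_min
  partly_child <- !is.na(age_min) & age_min < config$child_age_max
  partly_elderly <- !is.na(age_max) & age_max > config$elderly_age_min
  vulnerability <- ifelse(entirely_child | entirely_elderly, 3L,
                          ifelse(partly_child | partly_elderly, 2L, 1L))
  vulnerability[is.na(age_min) & is.na(age_max)] <- NA_integer_

  media <- media_attention %in% TRUE
  fora <- patient_forum_reports %in% TRUE
  contact <- patient_contact_notes %in% TRUE
  trust <- ifelse(media | fora, 3L, ifelse(contact, 2L, 1L))

  tibble::tibble(
    vulnerability = as.integer(vulnerability),
    trust = as.integer(trust),
    susceptibility = as.integer(pmax(vulnerability, trust, na.rm = TRUE))
  )
}

#' Cohort-relative cost thresholds
#'
#' The cost of the alternative treatment is expressed as a percentage of the
#' cost of the treatment in shortage. The rating is relative to the cohort:
#' ratios above the cohort's upper quartile rate high and below the lower
#' quartile rate low. Quartiles are computed by linear interpolation on the
#' sorted sample (R's default type 7), and the method label travels with the
#' thresholds for provenance.
#'
#' @param ratios Numeric vector of cost ratios in percent (missing values
#'   dropped). At least 4 non-missing ratios are required; with fewer, supply
#'   explicit thresholds via [cost_thresholds()].
#' @param config A [rater_config()].
#' @return A `cost_thresholds` object with fields `q1`, `q3`, `median`,
#'   `n_ratios` and `method_label`.
#' @export
compute_cost_thresholds <- function(ratios, config = rater_config()) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 4) {
    abort(paste0(
      "Cohort-relative cost thresholds need at least 4 non-missing cost ratios (got ",
      length(ratios), "). Supply explicit thresholds with cost_thresholds(q1, q3)."),
      class = "cost_threshold_error")
  }
  q <- unname(quantile(ratios, probs = c(0.25, 0.5, 0.75), type = 7))
  cost_thresholds(q1 = q[1], q3 = q[3], median = q[2], n_ratios = length(ratios))
}

#' Explicit cost thresholds
#' @param q1,q3 Lower and upper quartile of the cost-ratio distribution, in
#'   percent.
#' @param median Optional median ratio (informational).
#' @param n_ratios Number of ratios the quartiles were computed from.
#' @param method_label Provenance label for the quartile estimator.
#' @return A `cost_thresholds` object.
#' @export
cost_thresholds <- function(q1, q3, median = NA_real_, n_ratios = NA_integer_,
                            method_label = "type7_linear_interpolation") {
  if (q1 > q3) abort("q1 must not exceed q3.")
  structure(list(q1 = q1, q3 = q3, median = median,
                 n_ratios = n_ratios, method_label = method_label),
            class = "cost_thresholds")
}

#' @export
print.cost_thresholds <- function(x, ...) {
  cat("<cost_thresholds> q1 = ", format(x$q1), "%, q3 = ", format(x$q3),
      "% (", x$method_label, ", n = ", x$n_ratios, ")\n", sep = "")
  invisible(x)
}

#' Rate the costs element
#'
#' Costs have a medicine aspect and a personnel aspect. The medicine aspect
#' compares the list price of the alternative to the product in shortage:
#' ratio = 100 * price_alternative / price_original, rated high strictly
#' above the cohort's upper quartile and low strictly below the lower
#' quartile (boundary values rate moderate). Personnel costs scale with the
#' work the switch creates for pharmacists and physicians and are therefore
#' rated at the same level as the alternative-product element. The element is
#' the maximum of the two aspects; with missing prices (or no alternative)
#' the medicine aspect is omitted and the personnel aspect stands alone.
#'
#' @param price_original,price_alternative Prices per defined treatment unit;
#'   may be missing.
#' @param thresholds A `cost_thresholds` object.
#' @param alternative_rating Integer rating of the alternative-product
#'   element (personnel aspect).
#' @return A tibble with integer columns `medicine_cost` (NA when omitted),
#'   `personnel_cost` and `costs` (the element rating).
#' @export
rate_costs <- function(price_original, price_alternative, thresholds,
                       alternative_rating) {
  stopifnot(inherits(thresholds, "cost_thresholds"))
  alternative_rating <- assert_rating(alternative_rating, "alternative_rating")
  zero_orig <- !is.na(price_original) & price_original == 0
  if (any(zero_orig)) {
    warn(paste0("rate_costs: price_original is 0 for ", sum(zero_orig),
                " record(s); cost ratio undefined, medicine-cost aspect omitted."))
  }
  ratio <- ifelse(is.na(price_original) | is.na(price_alternative) | zero_orig,
                  NA_real_, 100 * price_alternative / price_original)
  medicine <- ifelse(is.na(ratio), NA_integer_,
                     ifelse(ratio > thresholds$q3, 3L,
                            ifelse(ratio < thresholds$q1, 1L, 2L)))
  costs <- as.integer(pmax(medicine, alternative_rating, na.rm = TRUE))
  tibble::tibble(
    medicine_cost = as.integer(medicine),
    personnel_cost = alternative_rating,
    costs = costs
  )
}

#' Rate the number-of-patients element
#'
#' Based on how many people used the product in the year before the shortage.
#' An orphan indication implies few patients and rates low, taking precedence
#' over any other rule. Hospital products without usage statistics rate
#' moderate by default. Otherwise the prior-year user count is cut at
#' `config$n_patients_low_max` (at or below: low) and
#' `config$n_patients_high_min` (at or above: high).
#'
#' @param users_prior_year Prior-year user count; may be missing for hospital
#'   or orphan products.
#' @param hospital_product,orphan_indication Logical flags.
#' @param config A [rater_config()].
#' @return Integer ratings in `{1, 2, 3}`.
#' @export
rate_n_patients <- function(users_prior_year, hospital_product = FALSE,
                            orphan_indication = FALSE,
                            config = rater_config()) {
  n <- max(length(users_prior_year), length(hospital_product),
           length(orphan_indication))
  orphan <- rep_len(orphan_indication %in% TRUE, n)
  hospital <- rep_len(hospital_product %in% TRUE, n)
  users_prior_year <- rep_len(users_prior_year, n)
  no_count <- is.na(users_prior_year)
  unratable <- no_count & !hospital & !orphan
  if (any(unratable)) {
    abort(paste0("rate_n_patients: ", sum(unratable),
                 " record(s) have no user count and neither hospital_product nor ",
                 "orphan_indication set; supply a count or a flag."),
          class = "rating_error")
  }
  ifelse(orphan, 1L,
         ifelse(hospital & no_count, 2L,
                ifelse(users_prior_year <= config$n_patients_low_max, 1L,
                       ifelse(users_prior_year >= config$n_patients_high_min,
                              3L, 2L))))
}

#' Construct an element profile
#'
#' The five element ratings of one shortage, with optional aspect-level
#' sub-ratings. Construction enforces the max-over-aspects rule (each element
#' equals the maximum of its present aspects) and the personnel-cost
#' convention (the personnel aspect equals the alternative-product rating).
#'
#' @param alternative,disease,susceptibility,costs,n_patients Integer ratings
#'   in `{1, 2, 3}`.
#' @param aspects Optional named list of aspect ratings; recognised names are
#'   `alternative_primary`, `alternative_secondary`, `vulnerability`,
#'   `trust`, `medicine_cost`, `personnel_cost`.
#' @return An object of class `element_profile`.
#' @export
element_profile <- function(alternative, disease, susceptibility, costs,
                            n_patients, aspects = NULL) {
  ratings <- c(alternative = assert_rating(alternative, "alternative"),
               disease = assert_rating(disease, "disease"),
               susceptibility = assert_rating(susceptibility, "susceptibility"),
               costs = assert_rating(costs, "costs"),
               n_patients = assert_rating(n_patients, "n_patients"))
  if (anyNA(ratings)) {
    abort(paste0("Element profile incomplete: missing rating for ",
                 paste(names(ratings)[is.na(ratings)], collapse = ", ")),
          class = "aggregation_error")
  }
  if (!is.null(aspects)) {
    aspects <- lapply(aspects, assert_rating, what = "aspect rating")
    check_max <- function(element, aspect_names) {
      present <- intersect(aspect_names, names(aspects))
      present <- present[!vapply(aspects[present], anyNA, logical(1))]
      if (length(present) > 0 &&
          ratings[[element]] != max(unlist(aspects[present]))) {
        abort(paste0("Element '", element,
                     "' must equal the maximum of its aspect ratings."))
      }
    }
    check_max("alternative", c("alternative_primary", "alternative_secondary"))
    check_max("susceptibility", c("vulnerability", "trust"))
    check_max("costs", c("medicine_cost", "personnel_cost"))
    if (!is.null(aspects$personnel_cost) && !is.na(aspects$personnel_cost) &&
        aspects$personnel_cost != ratings[["alternative"]]) {
      abort("personnel_cost aspect must equal the alternative-product rating.")
    }
  }
  structure(list(ratings = ratings, aspects = aspects),
            class = "element_profile")
}

#' @export
print.element_profile <- function(x, ...) {
  cat("<element_profile> ",
      paste(names(x$ratings), x$ratings, sep = "=", collapse = " "), "\n",
      sep = "")
  if (!is.null(x$aspects)) {
    cat("  aspects: ",
        paste(names(x$aspects), unlist(x$aspects), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Rate a single shortage record on all five elements
#'
#' Composes the five element raters. An `element_profile` passed in is
#' returned unchanged (bypass mode for pre-rated data).
#'
#' @param record A one-row data frame (or named list) with the registry
#'   fields, or an [element_profile()].
#' @param thresholds A `cost_thresholds` object (cohort-relative; see
#'   [compute_cost_thresholds()]).
#' @param config A [rater_config()].
#' @return An [element_profile()] with aspect ratings retained for the ECHO
#'   rollup.
#' @export
rate_record <- function(record, thresholds, config = rater_config()) {
  if (inherits(record, "element_profile")) return(record)
  record <- as.list(record)
  with_element <- function(element, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Failed to rate element '", element, "': ",
                   conditionMessage(e)), parent = e)
    })
  }
  alt <- with_element("alternative",
    rate_alternative_product(record$solution_category, config))
  dis <- with_element("disease", rate_disease(record$disease_severity, config))
  sus <- with_element("susceptibility", rate_susceptibility(
    record$age_min, record$age_max,
    record$patient_contact_notes %||% FALSE,
    record$media_attention %||% FALSE,
    record$patient_forum_reports %||% FALSE, config))
  cst <- with_element("costs", rate_costs(
    record$price_original %||% NA_real_,
    record$price_alternative %||% NA_real_, thresholds, alt))
  npt <- with_element("n_patients", rate_n_patients(
    record$users_prior_year %||% NA_real_,
    record$hospital_product %||% FALSE,
    record$orphan_indication %||% FALSE, config))
  element_profile(
    alternative = alt, disease = dis, susceptibility = sus$susceptibility,
    costs = cst$costs, n_patients = npt,
    aspects = list(vulnerability = sus$vulnerability, trust = sus$trust,
                   medicine_cost = cst$medicine_cost,
                   personnel_cost = cst$personnel_cost))
}

#' Rate every record of a cohort
#'
#' Computes cohort-relative cost thresholds from the cohort's own price
#' ratios (unless explicit thresholds are supplied) and rates all records.
#' Aspect ratings are kept as columns for the ECHO rollup.
#'
#' @param cohort A [shortage_cohort()].
#' @param config A [rater_config()].
#' @param thresholds Optional explicit `cost_thresholds`; by default they are
#'   recomputed from this cohort.
#' @return A tibble: the registry columns plus `cost_ratio`, the aspect
#'   columns (`aspect_vulnerability`, `aspect_trust`, `aspect_medicine_cost`,
#'   `aspect_personnel_cost`) and the five element ratings
#'   (`rating_alternative`, `rating_disease`, `rating_susceptibility`,
#'   `rating_costs`, `rating_n_patients`). The thresholds and the
#'   configuration fingerprint are attached as attributes `cost_thresholds`
#'   and `config_fingerprint`.
#' @export
rate_cohort <- function(cohort, config = rater_config(), thresholds = NULL) {
  stopifnot(inherits(cohort, "shortage_cohort"))
  rec <- cohort$records
  ratio <- ifelse(is.na(rec$price_original) | is.na(rec$price_alternative) |
                    rec$price_original == 0, NA_real_,
                  100 * rec$price_alternative / rec$price_original)
  if (is.null(thresholds)) {
    thresholds <- compute_cost_thresholds(ratio, config)
  }
  alt <- rate_alternative_product(rec$solution_category, config)
  dis <- rate_disease(rec$disease_severity, config)
  sus <- rate_susceptibility(rec$age_min, rec$age_max,
                             rec$patient_contact_notes, rec$media_attention,
                             rec$patient_forum_reports, config)
  cst <- rate_costs(rec$price_original, rec$price_alternative, thresholds, alt)
  npt <- rate_n_patients(rec$users_prior_year, rec$hospital_product,
                         rec$orphan_indication, config)
  out <- dplyr::mutate(
    rec,
    cost_ratio = ratio,
    aspect_vulnerability = sus$vulnerability,
    aspect_trust = sus$trust,
    aspect_medicine_cost = cst$medicine_cost,
    aspect_personnel_cost = cst$personnel_cost,
    rating_alternative = as.integer(alt),
    rating_disease = as.integer(dis),
    rating_susceptibility = sus$susceptibility,
    rating_costs = cst$costs,
    rating_n_patients = as.integer(npt)
  )
  attr(out, "cost_thresholds") <- thresholds
  attr(out, "config_fingerprint") <- config_fingerprint(config)
  out
}
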