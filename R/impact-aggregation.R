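# Aggregation of the five element ratings into the overall impact score,
# the economic/clinical/humanistic (ECHO) outcome profile, and the
# direct/indirect/unforgiving classification flags.

#' Overall impact score of an element profile
#'
#' The five element ratings are multiplied into a single overall score.
#' Because each rating is 1, 2 or 3, the score ranges from 1 to 243 (3^5) and
#' multiplication sharply separates shortages with several high ratings from
#' the rest. An alternative additive aggregation (sum, range 5-15) is
#' provided for sensitivity analysis; it compresses the top of the scale and
#' is off by default.
#'
#' Classification flags: `direct_high` marks a high rating on the elements
#' that affect patients directly (alternative product or disease);
#' `indirect_high` marks a high rating on the indirect elements (costs,
#' susceptibility or number of patients).
#'
#' @param profile An [element_profile()], or anything accepted by it (a named
#'   list/one-row data frame with the five ratings).
#' @param method `"product"` (default) or `"sum"`.
#' @return An object of class `impact_score`: a list with `overall`,
#'   `n_high_elements`, `direct_high`, `indirect_high` and `method`.
#' @export
overall_score <- function(profile, method = c("product", "sum")) {
  method <- match.arg(method)
  profile <- as_element_profile(profile)
  r <- profile$ratings
  overall <- if (method == "product") prod(r) else sum(r)
  structure(list(
    overall = as.integer(overall),
    n_high_elements = as.integer(sum(r == 3L)),
    direct_high = r[["alternative"]] == 3L || r[["disease"]] == 3L,
    indirect_high = r[["costs"]] == 3L || r[["susceptibility"]] == 3L ||
      r[["n_patients"]] == 3L,
    method = method
  ), class = "impact_score")
}

#' @export
print.impact_score <- function(x, ...) {
  cat("<impact_score> overall = ", x$overall, " (", x$method, "), ",
      x$n_high_elements, " element(s) rated high; direct_high = ",
      x$direct_high, ", indirect_high = ", x$indirect_high, "\n", sep = "")
  invisible(x)
}

as_element_profile <- function(profile) {
  if (inherits(profile, "element_profile")) return(profile)
  p <- as.list(profile)
  # accept both bare and rating_-prefixed names
  pick <- function(name) p[[name]] %||% p[[paste0("rating_", name)]]
  elements <- c("alternative", "disease", "susceptibility", "costs",
                "n_patients")
  vals <- lapply(elements, pick)
  absent <- vapply(vals, is.null, logical(1))
  if (any(absent)) {
    abort(paste0("Element profile incomplete: missing rating for ",
                 paste(elements[absent], collapse = ", ")),
          class = "aggregation_error")
  }
  names(vals) <- elements
  aspect_names <- c("alternative_primary", "alternative_secondary",
                    "vulnerability", "trust", "medicine_cost",
                    "personnel_cost")
  aspects <- p[intersect(c(aspect_names, paste0("aspect_", aspect_names)),
                         names(p))]
  names(aspects) <- sub("^aspect_", "", names(aspects))
  do.call(element_profile,
          c(vals, list(aspects = if (length(aspects)) aspects else NULL)))
}

#' Roll element ratings up to ECHO outcomes
#'
#' The five elements trace back to the three outcome families of the ECHO
#' model. Economic outcomes collect costs and number of patients affected;
#' clinical outcomes collect disease, the primary aspects of the alternative
#' product (active substance, licensing, on/off-label use) and the
#' vulnerability aspect of susceptibility; humanistic outcomes collect the
#' secondary aspects of the alternative product (route, strength,
#' concentration) and trust in the alternative therapy. Within each outcome
#' the highest contributing rating is taken.
#'
#' When aspect-level ratings are not available the combined element rating
#' stands in for each of its aspect slots (an upper-bound convention,
#' recorded as "aspect fallback" in output metadata).
#'
#' @param profile An [element_profile()] (aspects used when present).
#' @return An object of class `echo_profile`: integer ratings `economic`,
#'   `clinical`, `humanistic` plus an `aspect_fallback` flag.
#' @export
echo_rollup <- function(profile) {
  profile <- as_element_profile(profile)
  r <- profile$ratings
  a <- profile$aspects %||% list()
  get_aspect <- function(name, fallback) {
    v <- a[[name]]
    if (is.null(v) || is.na(v)) fallback else v
  }
  fallback_used <- is.null(a$alternative_primary) ||
    is.null(a$alternative_secondary) || is.null(a$vulnerability) ||
    is.null(a$trust)
  economic <- max(r[["costs"]], r[["n_patients"]])
  clinical <- max(r[["disease"]],
                  get_aspect("alternative_primary", r[["alternative"]]),
                  get_aspect("vulnerability", r[["susceptibility"]]))
  humanistic <- max(get_aspect("alternative_secondary", r[["alternative"]]),
                    get_aspect("trust", r[["susceptibility"]]))
  structure(list(economic = as.integer(economic),
                 clinical = as.integer(clinical),
                 humanistic = as.integer(humanistic),
                 aspect_fallback = fallback_used),
            class = "echo_profile")
}

#' @export
print.echo_profile <- function(x, ...) {
  cat("<echo_profile> economic = ", x$economic, ", clinical = ", x$clinical,
      ", humanistic = ", x$humanistic,
      if (x$aspect_fallback) " (aspect fallback)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify an unforgiving shortage
#'
#' Shortages where a patient cannot miss a dose without harming the
#' treatment outcome tend to rate high on several elements at once; such
#' "unforgiving" shortages demand a prompt reaction. The default flags a
#' shortage with at least `k = 2` elements rated high.
#'
#' @param score An `impact_score` (or an [element_profile()], scored first).
#' @param k Minimum number of elements rated high (default 2).
#' @return Logical.
#' @export
classify_unforgiving <- function(score, k = 2) {
  if (k < 1) abort("k must be at least 1.")
  if (!inherits(score, "impact_score")) score <- overall_score(score)
  score$n_high_elements >= k
}

#' Aggregate scores over a rated cohort
#'
#' Vectorised aggregation for a scored table as produced by [rate_cohort()]
#' (or any table with the five `rating_*` columns, e.g. pre-rated data):
#' adds the overall multiplicative score, the count of elements rated high,
#' the direct/indirect/unforgiving flags and the three ECHO outcome ratings.
#' Aspect columns are used for the rollup when present; otherwise the
#' combined element ratings stand in.
#'
#' @param rated A data frame with integer columns `rating_alternative`,
#'   `rating_disease`, `rating_susceptibility`, `rating_costs`,
#'   `rating_n_patients`, optionally aspect columns `aspect_vulnerability`,
#'   `aspect_trust` (and `aspect_medicine_cost`, `aspect_personnel_cost`).
#' @param unforgiving_k Threshold for the unforgiving flag (default 2).
#' @param method Aggregation method, `"product"` (default) or `"sum"`.
#' @return The input tibble with columns `overall`, `n_high_elements`,
#'   `direct_high`, `indirect_high`, `unforgiving`, `echo_economic`,
#'   `echo_clinical`, `echo_humanistic` appended.
#' @export
aggregate_scores <- function(rated, unforgiving_k = 2,
                             method = c("product", "sum")) {
  method <- match.arg(method)
  rated <- tibble::as_tibble(rated)
  needed <- paste0("rating_", c("alternative", "disease", "susceptibility",
                                "costs", "n_patients"))
  missing_cols <- setdiff(needed, names(rated))
  if (length(missing_cols) > 0) {
    abort(paste0("Cannot aggregate: missing element rating column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "aggregation_error")
  }
  r <- lapply(rated[needed], assert_rating)
  if (anyNA(unlist(r))) {
    abort("Cannot aggregate: NA element ratings present.",
          class = "aggregation_error")
  }
  m <- do.call(cbind, r)
  overall <- if (method == "product") {
    as.integer(r[[1]] * r[[2]] * r[[3]] * r[[4]] * r[[5]])
  } else {
    as.integer(r[[1]] + r[[2]] + r[[3]] + r[[4]] + r[[5]])
  }
  n_high <- as.integer(rowSums(m == 3L))
  vuln <- if ("aspect_vulnerability" %in% names(rated)) {
    rated$aspect_vulnerability
  } else rated$rating_susceptibility
  trust <- if ("aspect_trust" %in% names(rated)) {
    rated$aspect_trust
  } else rated$rating_susceptibility
  vuln <- ifelse(is.na(vuln), rated$rating_susceptibility, vuln)
  trust <- ifelse(is.na(trust), rated$rating_susceptibility, trust)
  dplyr::mutate(
    rated,
    overall = overall,
    n_high_elements = n_high,
    direct_high = rating_alternative == 3L | rating_disease == 3L,
    indirect_high = rating_costs == 3L | rating_susceptibility == 3L |
      rating_n_patients == 3L,
    unforgiving = n_high >= unforgiving_k,
    echo_economic = pmax(rating_costs, rating_n_patients),
    echo_clinical = pmax(rating_disease, rating_alternative, as.integer(vuln)),
    echo_humanistic = pmax(rating_alternative, as.integer(trust))
  )
}
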