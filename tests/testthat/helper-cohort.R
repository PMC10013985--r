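# Builders for small in-code fixtures used across the test files.

# A single valid registry record as a named list; override any field.
make_record <- function(id = "S001", ...) {
  rec <- list(
    shortage_id = id,
    product_name = paste0("product_", id),
    atc_code = "N05AX08",
    route = "oral",
    originator = TRUE,
    start_date = as.Date("2013-03-01"),
    end_date = as.Date("2013-04-15"),
    solution_category = "therapeutic_substitution",
    disease_severity = "moderate",
    age_min = 20, age_max = 60,
    patient_contact_notes = FALSE,
    media_attention = FALSE,
    patient_forum_reports = FALSE,
    price_original = 10, price_alternative = 12,
    users_prior_year = 5000,
    hospital_product = FALSE,
    orphan_indication = FALSE
  )
  dots <- list(...)
  rec[names(dots)] <- dots
  rec
}

# A cohort built from per-record overrides, e.g.
# make_cohort(list(route = "oral"), list(route = "rectal"))
make_cohort <- function(..., provenance = "test fixture") {
  overrides <- list(...)
  rows <- lapply(seq_along(overrides), function(i) {
    args <- overrides[[i]]
    if (is.null(args$id)) args$id <- sprintf("S%03d", i)
    rec <- do.call(make_record, args)
    tibble::as_tibble(rec[lengths(rec) > 0])
  })
  shortage_cohort(dplyr::bind_rows(rows), provenance = provenance)
}

default_thresholds <- function() cost_thresholds(q1 = 80, q3 = 120)

# All 243 combinations of five ratings in {1,2,3}
all_profiles <- function() {
  expand.grid(rating_alternative = 1:3, rating_disease = 1:3,
              rating_susceptibility = 1:3, rating_costs = 1:3,
              rating_n_patients = 1:3)
}
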