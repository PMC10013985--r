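# Shortage registry data model: validated cohort container plus CSV I/O.

# Mandatory registry columns, in canonical order.
cohort_columns <- c(
  "shortage_id", "product_name", "atc_code", "route", "originator",
  "start_date", "end_date", "solution_category", "disease_severity",
  "age_min", "age_max", "patient_contact_notes", "media_attention",
  "patient_forum_reports", "price_original", "price_alternative",
  "users_prior_year", "hospital_product", "orphan_indication"
)

#' Construct a validated shortage cohort
#'
#' A cohort is an ordered collection of shortage episodes, one row per
#' episode, carrying every raw attribute needed to rate the five impact
#' elements. Construction validates types, controlled vocabularies and
#' cross-field invariants (dates ordered, ages ordered and non-negative,
#' prices and user counts non-negative, ATC main group one of the 14
#' anatomical letters, unique episode identifiers). Rows violating an
#' invariant are reported together with their row index.
#'
#' `disease_severity` may hold either a severity enumerant
#' (`mild`/`moderate`/`severe`/`multi_class`) or a disability weight in
#' \[0, 1\] written as a number; both forms are accepted by the disease rater.
#' An optional `product_type` column (e.g. `MA`, `parallel_import`,
#' `homeopathic`, `unregistered`) marks products outside the
#' marketing-authorisation definition; non-`MA` rows are dropped by
#' [filter_eligible()].
#'
#' @param records A data frame with the registry columns (see Details).
#' @param provenance Free-text label describing where the records came from.
#' @return An object of class `shortage_cohort`: a list with elements
#'   `records` (a tibble) and `provenance`.
#' @seealso [read_cohort()], [write_cohort()], [filter_eligible()],
#'   [merge_episodes()]
#' @export
shortage_cohort <- function(records, provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Registry is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "shortage_schema_error")
  }
  records <- coerce_record_types(records)
  problems <- validate_records(records)
  if (length(problems) > 0) {
    abort(c("Invalid shortage records:", setNames(problems, rep("x", length(problems)))),
          class = "shortage_validation_error")
  }
  structure(list(records = records, provenance = provenance),
            class = "shortage_cohort")
}

coerce_record_types <- function(records) {
  chr <- function(x) as.character(x)
  lgl <- function(x) {
    if (is.character(x)) x <- tolower(x) %in% c("true", "t", "1", "yes")
    as.logical(x)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  dte <- function(x) {
    if (inherits(x, "Date")) return(x)
    as.Date(as.character(x), format = "%Y-%m-%d")
  }
  records$shortage_id <- chr(records$shortage_id)
  records$product_name <- chr(records$product_name)
  records$atc_code <- chr(records$atc_code)
  records$route <- chr(records$route)
  records$solution_category <- chr(records$solution_category)
  records$disease_severity <- chr(records$disease_severity)
  records$originator <- lgl(records$originator)
  for (col in c("patient_contact_notes", "media_attention",
                "patient_forum_reports", "hospital_product",
                "orphan_indication")) {
    records[[col]] <- lgl(records[[col]])
  }
  for (col in c("age_min", "age_max", "price_original", "price_alternative",
                "users_prior_year")) {
    records[[col]] <- num(records[[col]])
  }
  records$start_date <- dte(records$start_date)
  records$end_date <- dte(records$end_date)
  if ("product_type" %in% names(records)) {
    records$product_type <- chr(records$product_type)
  }
  records
}

# Returns a character vector of row-indexed problem descriptions (empty if valid).
validate_records <- function(records) {
  problems <- character()
  add <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      problems <<- c(problems, paste0(
        "row(s) ", paste(head(idx, 10), collapse = ", "),
        if (length(idx) > 10) ", ..." else "", ": ", msg))
    }
  }
  dup <- duplicated(records$shortage_id)
  add(dup, "duplicate shortage_id within cohort")
  add(is.na(records$shortage_id) | records$shortage_id == "",
      "missing shortage_id")
  add(!(records$route %in% shortage_vocab$route),
      paste0("route not in vocabulary {",
             paste(shortage_vocab$route, collapse = ", "), "}"))
  add(!(records$solution_category %in% shortage_vocab$solution_category),
      paste0("solution_category not in vocabulary {",
             paste(shortage_vocab$solution_category, collapse = ", "), "}"))
  add(!(toupper(substr(records$atc_code, 1, 1)) %in% shortage_vocab$atc_class),
      "ATC code must start with an anatomical main-group letter (A,B,C,D,G,H,J,L,M,N,P,R,S,V)")
  add(is.na(records$start_date), "missing or unparseable start_date (ISO-8601 expected)")
  add(!is.na(records$end_date) & records$end_date < records$start_date,
      "end_date before start_date")
  add(!is.na(records$age_min) & !is.na(records$age_max) &
        records$age_min > records$age_max, "age_min greater than age_max")
  add((!is.na(records$age_min) & records$age_min < 0) |
        (!is.na(records$age_max) & records$age_max < 0), "negative age")
  add((!is.na(records$price_original) & records$price_original < 0) |
        (!is.na(records$price_alternative) & records$price_alternative < 0),
      "negative price")
  add(!is.na(records$users_prior_year) & records$users_prior_year < 0,
      "negative users_prior_year")
  sev <- records$disease_severity
  sev_num <- suppressWarnings(as.numeric(sev))
  sev_ok <- sev %in% shortage_vocab$disease_severity |
    (!is.na(sev_num) & sev_num >= 0 & sev_num <= 1)
  add(!is.na(sev) & !sev_ok,
      "disease_severity must be mild/moderate/severe/multi_class or a disability weight in [0,1]")
  problems
}

#' @export
print.shortage_cohort <- function(x, ...) {
  cat("<shortage_cohort> ", nrow(x$records), " record(s); provenance: ",
      x$provenance, "\n", sep = "")
  print(x$records, ...)
  invisible(x)
}

#' Number of records in a cohort
#' @param cohort A [shortage_cohort()].
#' @return Integer count of shortage episodes.
#' @export
n_records <- function(cohort) nrow(cohort$records)

#' Read a shortage registry file
#'
#' Reads a delimited registry (comma-delimited UTF-8 by default, ISO-8601
#' dates, empty fields for missing values) and returns a validated cohort.
#' A missing mandatory column raises a schema error naming the column; rows
#' with out-of-vocabulary enumerants or broken invariants raise a
#' row-indexed validation error listing the allowed values.
#'
#' @param path Path to the registry file.
#' @param delim Field delimiter (default `","`; use `"\t"` for TSV).
#' @param provenance Provenance label; defaults to the file name.
#' @return A [shortage_cohort()].
#' @export
read_cohort <- function(path, delim = ",", provenance = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("Registry file not found: ", path))
  }
  records <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  shortage_cohort(records, provenance = provenance)
}

#' Write a shortage registry file
#'
#' Writes the cohort as comma-delimited UTF-8 with ISO-8601 dates and empty
#' fields for missing values; [read_cohort()] on the result reproduces the
#' cohort losslessly.
#'
#' @param cohort A [shortage_cohort()].
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "shortage_cohort"))
  out <- cohort$records
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  out$end_date <- ifelse(is.na(out$end_date), NA_character_,
                         format(out$end_date, "%Y-%m-%d"))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
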