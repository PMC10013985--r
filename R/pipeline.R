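# End-to-end pipeline: eligibility filter -> episode merge -> element rating
# -> aggregation; cohort summaries; run manifests for provenance.

#' Score a shortage cohort end to end
#'
#' Applies the eligibility filter (at least two weeks unavailable, authorised
#' products only), merges recurrences within 30 days, rates the five
#' elements with cohort-relative cost thresholds, and aggregates into the
#' overall impact score, classification flags and ECHO outcome ratings.
#'
#' If the registry already carries the five `rating_*` columns (pre-rated
#' data), rating is skipped and the ratings are aggregated as supplied.
#'
#' @param cohort A [shortage_cohort()], or a data frame with pre-rated
#'   `rating_*` columns.
#' @param config A [rater_config()].
#' @param thresholds Optional explicit `cost_thresholds`.
#' @param filter Apply [filter_eligible()] (default TRUE).
#' @param merge Apply [merge_episodes()] (default TRUE).
#' @return A scored tibble (see [rate_cohort()] and [aggregate_scores()])
#'   with the configuration fingerprint in attribute `config_fingerprint`.
#' @export
score_cohort <- function(cohort, config = rater_config(), thresholds = NULL,
                         filter = TRUE, merge = TRUE) {
  rating_cols <- paste0("rating_", c("alternative", "disease",
                                     "susceptibility", "costs", "n_patients"))
  if (is.data.frame(cohort) && all(rating_cols %in% names(cohort))) {
    out <- aggregate_scores(cohort)
    attr(out, "config_fingerprint") <- config_fingerprint(config)
    return(out)
  }
  stopifnot(inherits(cohort, "shortage_cohort"))
  if (filter) cohort <- filter_eligible(cohort)
  if (merge) cohort <- merge_episodes(cohort)
  rated <- rate_cohort(cohort, config = config, thresholds = thresholds)
  out <- aggregate_scores(rated)
  attr(out, "cost_thresholds") <- attr(rated, "cost_thresholds")
  attr(out, "config_fingerprint") <- attr(rated, "config_fingerprint")
  out
}

#' Summarise a scored cohort
#'
#' The standard cohort report: rating and ECHO distributions, overall-score
#' summaries per stratum, and Kruskal-Wallis/Dunn comparisons across strata,
#' plus yearly trends.
#'
#' @param scored A scored tibble from [score_cohort()].
#' @param by Stratum variables to summarise over.
#' @param tests Run stratified score comparisons (default TRUE; switched off
#'   automatically for strata with fewer than 2 levels).
#' @param p_adjust Adjustment label for the pairwise Dunn tests.
#' @return A list of class `cohort_summary`: `n`, `overall` (one-row tibble
#'   with median and quartiles of the overall score), `distribution` (a
#'   [rating_distribution()]), `scores_by` (named list of
#'   [stratified_scores()] tables), `tests_by` (named list of
#'   [compare_strata()] tables) and `trends` ([yearly_trends()]).
#' @export
summarize_cohort <- function(scored,
                             by = c("route", "atc_class", "year",
                                    "originator"),
                             tests = TRUE,
                             p_adjust = c("bonferroni", "holm", "none")) {
  p_adjust <- match.arg(p_adjust)
  scored <- tibble::as_tibble(scored)
  q <- unname(quantile(scored$overall, probs = c(0.25, 0.5, 0.75), type = 7))
  overall <- tibble::tibble(n = nrow(scored), median = q[2],
                            q1 = q[1], q3 = q[3])
  scores_by <- lapply(setNames(by, by), stratified_scores, scored = scored)
  tests_by <- list()
  if (tests) {
    for (v in by) {
      strata <- stratum_values(scored, v)
      if (length(unique(strata[!is.na(strata)])) >= 2) {
        tests_by[[v]] <- compare_strata(scored, v, p_adjust = p_adjust)
      }
    }
  }
  structure(list(
    n = nrow(scored), overall = overall,
    distribution = rating_distribution(scored),
    scores_by = scores_by, tests_by = tests_by,
    trends = yearly_trends(scored)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n = ", x$n, "; overall score median ",
      x$overall$median, " (IQR: ", x$overall$q1, "-", x$overall$q3, ")\n",
      sep = "")
  print(x$distribution)
  invisible(x)
}

#' Write a cohort summary to CSV tables and a JSON digest
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  put(summary$overall, "overall_score")
  put(summary$distribution$elements, "element_rating_distribution")
  if (!is.null(summary$distribution$echo)) {
    put(summary$distribution$echo, "echo_rating_distribution")
  }
  put(summary$distribution$summary, "summary_shares")
  for (v in names(summary$scores_by)) {
    put(summary$scores_by[[v]], paste0("scores_by_", v))
  }
  for (v in names(summary$tests_by)) {
    put(summary$tests_by[[v]], paste0("tests_by_", v))
  }
  put(summary$trends$scores, "yearly_scores")
  put(summary$trends$ratings, "yearly_rating_distribution")
  digest <- list(
    n = summary$n,
    overall = as.list(summary$overall),
    shares = setNames(as.list(summary$distribution$summary$pct),
                      summary$distribution$summary$share))
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(digest, jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)
  invisible(paths)
}

#' Create a run manifest
#'
#' A manifest ties every output file to the command, effective
#' configuration fingerprint, seeds, inputs and package version that
#' produced it.
#'
#' @param command Short name of the operation (e.g. `"score"`).
#' @param config The effective [rater_config()] or [generator_spec()].
#' @param seed Seed(s) used, if any.
#' @param inputs,outputs Character vectors of file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed = NULL,
                         inputs = character(0), outputs = character(0)) {
  structure(list(
    command = command,
    config_fingerprint = config_fingerprint(config),
    seed = seed,
    inputs = inputs, outputs = outputs,
    package_version = as.character(utils::packageVersion("shortageimpact")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Published element ratings of the highest-impact Dutch shortages
#'
#' The 17 products in the Dutch 2012-2015 cohort whose overall patient
#' impact score reached the reporting threshold of 36 or higher, with their
#' ATC main group, route of administration, originator/generic status, the
#' five published element ratings and the published overall score. Useful
#' as a worked example of the multiplicative aggregation and as a check of
#' the scoring arithmetic.
#'
#' @return A tibble with one row per product.
#' @export
high_impact_examples <- function() {
  path <- system.file("extdata", "dutch_high_impact_2012_2015.csv",
                      package = "shortageimpact", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
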