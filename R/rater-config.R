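# Rater configuration: the numeric cutpoints and category ladders that the
# rating framework leaves open, collected in one overridable, serialisable
# object so every scored output can be traced to its effective settings.

#' Configuration of the element raters
#'
#' The rating framework fixes the ordinal scale (1 = low, 2 = moderate,
#' 3 = high) and the max-over-aspects rule but leaves several numeric
#' cutpoints open. They live here, with defaults, so that every rated output
#' is reproducible and the effective settings can be echoed into results.
#'
#' @param disability_low_max Disability weights at or below this rate the
#'   disease low (default 0.10).
#' @param disability_high_min Disability weights strictly above this rate the
#'   disease high (default 0.30); in-between weights rate moderate.
#' @param child_age_max Age (years) below which patients count as children
#'   (default 18).
#' @param elderly_age_min Age (years) above which patients count as elderly
#'   (default 65). A population confined to children or to the elderly rates
#'   vulnerability high; one including them alongside adults rates moderate;
#'   adults only rates low.
#' @param n_patients_low_max Prior-year user counts at or below this rate the
#'   number of patients low (default 1,000).
#' @param n_patients_high_min Prior-year user counts at or above this rate
#'   high (default 100,000).
#' @param quartile_method Quartile estimator label; `"linear"` is linear
#'   interpolation on the sorted sample (R's type 7), the only method
#'   currently implemented.
#' @param solution_ladder Named integer vector mapping proposed-solution
#'   categories to alternative-product ratings. The default follows the
#'   pharmacy-practice preference ladder: generic substitution is the least
#'   disruptive solution (1); therapeutic substitution and unlicensed
#'   products both disrupt treatment materially (2); absence of any suitable
#'   therapy is the worst case (3).
#' @param dunn_adjust Multiplicity adjustment for pairwise Dunn tests:
#'   `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return An object of class `rater_config` (a named list).
#' @export
rater_config <- function(disability_low_max = 0.10,
                         disability_high_min = 0.30,
                         child_age_max = 18,
                         elderly_age_min = 65,
                         n_patients_low_max = 1000,
                         n_patients_high_min = 100000,
                         quartile_method = "linear",
                         solution_ladder = c(generic_substitution = 1L,
                                             therapeutic_substitution = 2L,
                                             unlicensed_product = 2L,
                                             no_therapy = 3L),
                         dunn_adjust = c("bonferroni", "holm", "none")) {
  dunn_adjust <- match.arg(dunn_adjust)
  quartile_method <- match.arg(quartile_method, "linear")
  if (!(disability_low_max < disability_high_min)) {
    abort("disability_low_max must be strictly below disability_high_min.")
  }
  if (!(n_patients_low_max < n_patients_high_min)) {
    abort("n_patients_low_max must be strictly below n_patients_high_min.")
  }
  if (!(child_age_max < elderly_age_min)) {
    abort("child_age_max must be strictly below elderly_age_min.")
  }
  ladder <- as.integer(solution_ladder)
  names(ladder) <- names(solution_ladder)
  if (!setequal(names(ladder), shortage_vocab$solution_category) ||
      !all(ladder %in% 1:3)) {
    abort("solution_ladder must map every solution category to a rating in {1,2,3}.")
  }
  structure(list(
    disability_low_max = disability_low_max,
    disability_high_min = disability_high_min,
    child_age_max = child_age_max,
    elderly_age_min = elderly_age_min,
    n_patients_low_max = n_patients_low_max,
    n_patients_high_min = n_patients_high_min,
    quartile_method = quartile_method,
    solution_ladder = ladder,
    dunn_adjust = dunn_adjust
  ), class = "rater_config")
}

#' @export
print.rater_config <- function(x, ...) {
  cat("<rater_config> fingerprint", config_fingerprint(x), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Write a rater configuration to YAML
#' @param config A [rater_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rater_config <- function(config, path) {
  stopifnot(inherits(config, "rater_config"))
  x <- unclass(config)
  x$solution_ladder <- as.list(x$solution_ladder)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a rater configuration from YAML
#'
#' Fields absent from the file keep their package defaults.
#'
#' @param path Path to a YAML file as written by [write_rater_config()].
#' @return A [rater_config()].
#' @export
read_rater_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$solution_ladder)) {
    x$solution_ladder <- unlist(x$solution_ladder)
  }
  do.call(rater_config, x)
}

#' Fingerprint of an effective configuration
#'
#' MD5 hash of the canonical JSON serialisation, used in run manifests and
#' scored outputs so every number is traceable to the settings that produced
#' it.
#'
#' @param config A [rater_config()], [generator_spec()] or any serialisable
#'   list.
#' @return A 32-character hex string.
#' @export
config_fingerprint <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}
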