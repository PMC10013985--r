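# Episode logic: eligibility filtering and the 30-day merge rule.

#' Filter a cohort down to eligible shortage episodes
#'
#' A shortage is an authorised product that is nationally unavailable for at
#' least two weeks; shorter gaps are normally absorbed by stock remaining in
#' the supply chain. Duration is counted inclusively on both ends (a shortage
#' starting 1 Jan and resolved 14 Jan lasted 14 days). Episodes with no end
#' date are ongoing and retained, because impact is rated at the start of the
#' shortage. If the optional `product_type` column is present, rows whose
#' type is not `"MA"` (parallel imports, homeopathic/herbal medicines,
#' unregistered products) are dropped as outside the shortage definition.
#'
#' @param cohort A [shortage_cohort()].
#' @param min_days Minimum eligible duration in days (default 14).
#' @return The filtered [shortage_cohort()]; counts of removed records are
#'   reported via a message.
#' @export
filter_eligible <- function(cohort, min_days = 14) {
  stopifnot(inherits(cohort, "shortage_cohort"))
  rec <- cohort$records
  n0 <- nrow(rec)
  n_type <- 0L
  if ("product_type" %in% names(rec)) {
    keep_type <- is.na(rec$product_type) | rec$product_type == "MA"
    n_type <- sum(!keep_type)
    rec <- rec[keep_type, , drop = FALSE]
  }
  duration <- as.numeric(rec$end_date - rec$start_date) + 1
  keep <- is.na(rec$end_date) | duration >= min_days
  n_short <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (n_type + n_short > 0) {
    inform(paste0("filter_eligible: removed ", n_short, " episode(s) shorter than ",
                  min_days, " days and ", n_type, " non-MA product(s); ",
                  nrow(rec), " of ", n0, " record(s) retained."))
  }
  cohort$records <- rec
  cohort
}

#' Merge recurring episodes of the same product
#'
#' A shortage reported within 30 days of the resolution of a previous
#' shortage of the same product (same product name and ATC code) is treated
#' as a continuation of that shortage; after more than 30 days it is a new
#' shortage. Consecutive episodes with a gap of at most `max_gap` days
#' (measured as next start minus previous end, in whole days; a gap of
#' exactly 30 merges) are collapsed into a single record spanning the
#' earliest start to the latest end. An episode with no end date is open and
#' absorbs every later episode of the same product. Overlapping episodes are
#' merged with a warning. The operation is idempotent.
#'
#' @param cohort A [shortage_cohort()].
#' @param max_gap Maximum merge gap in days (default 30).
#' @return A [shortage_cohort()] with merged episodes, ordered by product and
#'   start date. The merged record keeps the attributes of the earliest
#'   episode.
#' @export
merge_episodes <- function(cohort, max_gap = 30) {
  stopifnot(inherits(cohort, "shortage_cohort"))
  rec <- cohort$records
  if (nrow(rec) < 2) return(cohort)
  key <- paste(rec$product_name, toupper(rec$atc_code), sep = "\r")
  ord <- order(key, rec$start_date)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]

  n <- nrow(rec)
  group <- integer(n)
  group[1] <- 1L
  overlap <- FALSE
  cur_end <- rec$end_date[1]
  for (i in seq_len(n)[-1]) {
    new_product <- key[i] != key[i - 1]
    if (new_product) {
      group[i] <- group[i - 1] + 1L
      cur_end <- rec$end_date[i]
      next
    }
    gap <- if (is.na(cur_end)) -Inf else as.numeric(rec$start_date[i] - cur_end)
    if (gap <= max_gap) {
      group[i] <- group[i - 1]
      if (gap < 0) overlap <- TRUE
      # extend the open interval; an NA end keeps the episode open
      cur_end <- if (is.na(cur_end) || is.na(rec$end_date[i])) {
        as.Date(NA)
      } else {
        max(cur_end, rec$end_date[i])
      }
    } else {
      group[i] <- group[i - 1] + 1L
      cur_end <- rec$end_date[i]
    }
  }
  if (overlap) {
    warn("merge_episodes: overlapping episodes for the same product were merged.")
  }

  merged <- lapply(split(seq_len(n), group), function(idx) {
    block <- rec[idx, , drop = FALSE]
    out <- block[1, , drop = FALSE]
    out$start_date <- min(block$start_date)
    out$end_date <- if (anyNA(block$end_date)) as.Date(NA) else max(block$end_date)
    out
  })
  merged <- dplyr::bind_rows(merged)
  n_merged <- n - nrow(merged)
  if (n_merged > 0) {
    inform(paste0("merge_episodes: merged ", n_merged,
                  " recurrence(s) within ", max_gap, " days; ",
                  nrow(merged), " episode(s) remain."))
  }
  cohort$records <- merged
  cohort
}
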