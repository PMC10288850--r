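#' Discard partial actigraph data from the day of enrollment
#'
#' Recording starts mid-day when the devices are strapped on, and the setup
#' itself leaves a large artifact, so all epochs before the first 13:00
#' day anchor at or after enrollment are removed. A trailing partial day is
#' trimmed as well so the record holds complete analysis days only.
#' Patients left with zero complete days are flagged `excluded`.
#'
#' @param record one patient record from an `actidel_cohort`.
#' @return The record with both arms truncated to complete days, `n_days`
#'   recomputed, and `excluded = TRUE` when no complete day remains.
#' @seealso [truncate_cohort()]
#' @export
truncate_enrollment_day <- function(record) {
  s <- record$series$paretic
  if (nrow(s) == 0L) {
    record$n_days <- 0L
    record$excluded <- TRUE
    return(record)
  }
  anchor <- first_anchor(s$timestamp[1L])
  off <- as.integer(round(as.numeric(s$timestamp - anchor, units = "mins")))
  n_days <- max(0L, (max(off) + 1L) %/% 1440L)
  keep <- off >= 0L & off < n_days * 1440L

  record$series <- lapply(record$series, function(es) es[keep, , drop = FALSE])
  if (!is.null(record$states)) record$states <- record$states[keep]
  record$anchor <- anchor
  record$n_days <- n_days
  record$excluded <- n_days == 0L
  record
}

#' Truncate every patient in a cohort and drop excluded ones
#'
#' @param cohort an `actidel_cohort`.
#' @return The cohort with all records truncated via
#'   [truncate_enrollment_day()]; patients without a complete day are
#'   removed and their ids recorded in the `excluded` attribute.
#' @export
truncate_cohort <- function(cohort) {
  cohort$patients <- lapply(cohort$patients, truncate_enrollment_day)
  excl <- names(cohort$patients)[vapply(cohort$patients,
                                        function(p) p$excluded, TRUE)]
  cohort$patients <- cohort$patients[setdiff(names(cohort$patients), excl)]
  cohort$labels <- cohort$labels[!cohort$labels$patient_id %in% excl, ]
  attr(cohort, "excluded") <- excl
  cohort
}
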