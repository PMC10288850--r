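#' Encode clinical covariates into model-ready day-level columns
#'
#' Static demographics and stroke covariates (age, sex, admission NIHSS,
#' hematoma volume, location flags, intraventricular hemorrhage, ICH score)
#' are validated and repeated across each patient's days; the daily
#' mechanical-ventilation flag varies by day. Hematoma location is two
#' non-exclusive indicators (`lobar`, `deep`) — mixed locations make both 1.
#'
#' @param profiles tibble with one row per patient: `patient_id`, `age`,
#'   `sex` (0/1), `nihss` (0-42), `ich_volume_cc` (>= 0), `lobar` (0/1),
#'   `deep` (0/1), `ivh` (0/1), `ich_score` (0-6).
#' @param daily tibble `patient_id`, `day_index`, `ventilated` (0/1), one
#'   row per patient-day.
#' @param include_ich_score keep the ICH score column (on by default).
#' @return A tibble with one row per (patient, day) and numeric feature
#'   columns.
#' @export
encode_clinical <- function(profiles, daily, include_ich_score = TRUE) {
  need <- c("patient_id", "age", "sex", "nihss", "ich_volume_cc",
            "lobar", "deep", "ivh", "ich_score")
  if (!all(need %in% names(profiles))) {
    stop("clinical profiles must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(profiles$nihss < 0 | profiles$nihss > 42)) {
    stop("nihss out of range 0-42 for patient ",
         profiles$patient_id[which(profiles$nihss < 0 |
                                     profiles$nihss > 42)[1L]],
         call. = FALSE)
  }
  if (any(profiles$ich_score < 0 | profiles$ich_score > 6)) {
    stop("ich_score out of range 0-6 for patient ",
         profiles$patient_id[which(profiles$ich_score < 0 |
                                     profiles$ich_score > 6)[1L]],
         call. = FALSE)
  }
  if (any(profiles$ich_volume_cc < 0)) {
    stop("ich_volume_cc must be non-negative", call. = FALSE)
  }
  flags <- c("sex", "lobar", "deep", "ivh")
  for (f in flags) {
    if (!all(profiles[[f]] %in% 0:1)) {
      stop(sprintf("`%s` must be 0/1", f), call. = FALSE)
    }
  }
  if (!all(daily$ventilated %in% 0:1)) {
    stop("`ventilated` must be 0/1", call. = FALSE)
  }
  if (anyDuplicated(daily[c("patient_id", "day_index")])) {
    stop("daily status must have one row per (patient_id, day_index)",
         call. = FALSE)
  }
  cols <- need
  if (!include_ich_score) cols <- setdiff(cols, "ich_score")
  out <- dplyr::inner_join(daily[c("patient_id", "day_index", "ventilated")],
                           profiles[cols], by = "patient_id")
  dplyr::mutate(out, dplyr::across(-c("patient_id", "day_index"),
                                   as.numeric))
}

#' Read a clinical covariate CSV
#' @param path CSV with the columns documented in [encode_clinical()].
#' @return A tibble of profiles.
#' @export
read_clinical_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(patient_id = "character")))
}
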