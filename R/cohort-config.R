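#' Configuration for a synthetic actigraphy cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the structure of a moderate-to-severe intracerebral
#' hemorrhage cohort monitored on both wrists: 39 patients, stay lengths
#' with median near 5 days and a wide spread, 71% of days delirium-positive,
#' roughly 38% of patients delirious throughout and 15% never delirious.
#'
#' @param n_patients number of patients.
#' @param days_per_patient either a single non-negative integer (every
#'   patient monitored that many complete days) or a list
#'   `list(dist = "nbinom", size, mu, min)` describing a negative-binomial
#'   draw of complete monitoring days, truncated below at `min`.
#' @param delirium_prevalence_day target fraction of monitored days labeled
#'   delirious, in `[0, 1]`.
#' @param frac_always_delirious,frac_never_delirious fractions of patients
#'   delirious on every day / on no day; their sum must be at most 1. The
#'   remaining patients fluctuate day to day.
#' @param effect_size non-negative scalar scaling the delirium signal
#'   (night-time sleep fragmentation). `0` means delirium labels have no
#'   effect on the generated activity.
#' @param paresis_attenuation factor in `[0, 1]` multiplying patient-initiated
#'   activity in the paretic arm. Care-event activity is not attenuated: it
#'   is externally mediated.
#' @param care_event_rate expected care events (nursing checks, repositioning)
#'   per hour; events recur quasi-periodically.
#' @param care_event_jitter_sd SD, in minutes, of the Gaussian jitter applied
#'   to each scheduled care-event time.
#' @param gap_spec `list(prob_per_day, duration_min)`: probability that a
#'   monitoring day contains one device-removal gap (e.g. for MRI) and the
#'   gap duration in minutes. Gap epochs are missing in both arms, never zero.
#' @param weekend_gaps if `TRUE`, days whose assessment falls on a weekend
#'   are marked `assessed = 0` (no delirium rating available).
#' @param rng_seed integer seed; identical configurations reproduce
#'   identical cohorts bit for bit.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cohort_config(n_patients = 4, days_per_patient = 3, rng_seed = 1)
cohort_config <- function(n_patients = 39,
                          days_per_patient = list(dist = "nbinom",
                                                  size = 1.2, mu = 7,
                                                  min = 1),
                          delirium_prevalence_day = 0.71,
                          frac_always_delirious = 15 / 39,
                          frac_never_delirious = 6 / 39,
                          effect_size = 1,
                          paresis_attenuation = 0.3,
                          care_event_rate = 0.5,
                          care_event_jitter_sd = 10,
                          gap_spec = list(prob_per_day = 0.15,
                                          duration_min = 60),
                          weekend_gaps = FALSE,
                          rng_seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1 || n_patients != floor(n_patients)) {
    stop("invalid `n_patients`: must be a positive integer", call. = FALSE)
  }
  if (is.numeric(days_per_patient) && length(days_per_patient) == 1L) {
    if (is.na(days_per_patient) || days_per_patient < 0 ||
        days_per_patient != floor(days_per_patient)) {
      stop("invalid `days_per_patient`: fixed value must be a non-negative integer",
           call. = FALSE)
    }
  } else if (is.list(days_per_patient)) {
    need <- c("dist", "size", "mu", "min")
    if (!all(need %in% names(days_per_patient)) ||
        !identical(days_per_patient$dist, "nbinom") ||
        days_per_patient$size <= 0 || days_per_patient$mu <= 0 ||
        days_per_patient$min < 0) {
      stop("invalid `days_per_patient`: list form must be list(dist = \"nbinom\", size > 0, mu > 0, min >= 0)",
           call. = FALSE)
    }
  } else {
    stop("invalid `days_per_patient`: must be an integer or a distribution list",
         call. = FALSE)
  }
  .assert_scalar_frac(delirium_prevalence_day, "delirium_prevalence_day")
  .assert_scalar_frac(frac_always_delirious, "frac_always_delirious")
  .assert_scalar_frac(frac_never_delirious, "frac_never_delirious")
  if (frac_always_delirious + frac_never_delirious > 1) {
    stop("invalid `frac_always_delirious`/`frac_never_delirious`: fractions sum to more than 1",
         call. = FALSE)
  }
  .assert_scalar_frac(effect_size, "effect_size", 0, Inf)
  .assert_scalar_frac(paresis_attenuation, "paresis_attenuation")
  .assert_scalar_frac(care_event_rate, "care_event_rate", 0, Inf)
  .assert_scalar_frac(care_event_jitter_sd, "care_event_jitter_sd", 0, Inf)
  if (!is.list(gap_spec) ||
      !all(c("prob_per_day", "duration_min") %in% names(gap_spec))) {
    stop("invalid `gap_spec`: must be list(prob_per_day, duration_min)",
         call. = FALSE)
  }
  .assert_scalar_frac(gap_spec$prob_per_day, "gap_spec$prob_per_day")
  .assert_scalar_frac(gap_spec$duration_min, "gap_spec$duration_min", 0, 1440)
  if (!is.logical(weekend_gaps) || length(weekend_gaps) != 1L ||
      is.na(weekend_gaps)) {
    stop("invalid `weekend_gaps`: must be TRUE or FALSE", call. = FALSE)
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || is.na(rng_seed) ||
      rng_seed != floor(rng_seed)) {
    stop("invalid `rng_seed`: must be an integer", call. = FALSE)
  }

  structure(
    list(
      n_patients = as.integer(n_patients),
      days_per_patient = days_per_patient,
      delirium_prevalence_day = delirium_prevalence_day,
      frac_always_delirious = frac_always_delirious,
      frac_never_delirious = frac_never_delirious,
      effect_size = effect_size,
      paresis_attenuation = paresis_attenuation,
      care_event_rate = care_event_rate,
      care_event_jitter_sd = care_event_jitter_sd,
      gap_spec = gap_spec,
      weekend_gaps = weekend_gaps,
      rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  days <- if (is.numeric(x$days_per_patient)) {
    sprintf("fixed %d", as.integer(x$days_per_patient))
  } else {
    sprintf("nbinom(size = %g, mu = %g, min %d)",
            x$days_per_patient$size, x$days_per_patient$mu,
            as.integer(x$days_per_patient$min))
  }
  cat("<cohort_config>\n",
      sprintf("  patients: %d, days/patient: %s\n", x$n_patients, days),
      sprintf("  day prevalence %.2f (always %.2f / never %.2f of patients)\n",
              x$delirium_prevalence_day, x$frac_always_delirious,
              x$frac_never_delirious),
      sprintf("  effect_size %.2f, paresis_attenuation %.2f\n",
              x$effect_size, x$paresis_attenuation),
      sprintf("  care events %.2f/h (jitter sd %.0f min), gaps p=%.2f x %.0f min\n",
              x$care_event_rate, x$care_event_jitter_sd,
              x$gap_spec$prob_per_day, x$gap_spec$duration_min),
      sprintf("  seed %d\n", x$rng_seed), sep = "")
  invisible(x)
}
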