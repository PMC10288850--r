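#' Generate a synthetic bilateral-actigraphy cohort
#'
#' Simulates minute-epoch activity recordings (PIM and ZCM channels) for
#' both wrists of each patient, together with day-level delirium labels,
#' static clinical covariates and daily ventilation status. The activity
#' model is a two-state (rest/wake) Markov chain with circadian transition
#' probabilities: long consolidated rest overnight (22:00-06:00) and
#' alternating quiet/active bouts by day. On delirium-labeled days the
#' night-time chain is fragmented — the rest-to-wake rate is multiplied by
#' `1 + 2 * effect_size` and the wake-to-rest rate divided by
#' `1 + effect_size` — raising night activity and lowering the proportion
#' of zero-PIM epochs in proportion to `effect_size`. Patient-initiated
#' wake activity in the paretic arm is multiplied by `paresis_attenuation`;
#' quasi-periodic care events add unattenuated bursts to both arms at
#' shared, jittered times; device-removal gaps make both arms missing.
#' ZCM is drawn as Poisson with rate proportional to PIM.
#'
#' Epochs run from a random daytime enrollment moment on day 0 until
#' discharge at the 13:00 anchor closing the patient's last complete
#' monitoring day, so records include the partial enrollment day that
#' [truncate_enrollment_day()] removes.
#'
#' @param config a [cohort_config()].
#' @return An object of class `"actidel_cohort"`: a list with elements
#'   `patients` (named list of patient records, each holding paretic and
#'   non-paretic epoch series, per-epoch latent states, labels, clinical
#'   profile and daily ventilation), `labels` (one tibble across patients),
#'   `groups` (per-patient delirium trajectory class) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, days_per_patient = 2,
#'                                      rng_seed = 42))
#' names(coh$patients)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config object", call. = FALSE)
  }
  set.seed(config$rng_seed)
  n <- config$n_patients
  origin <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC")  # a Monday

  days <- .draw_days(config$days_per_patient, n)
  groups <- .assign_groups(n, config$frac_always_delirious,
                           config$frac_never_delirious)
  p_flux <- .fluctuating_day_prob(config)

  patients <- vector("list", n)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    patients[[i]] <- .simulate_patient(ids[i], days[i], groups[i], p_flux,
                                       config, origin)
  }
  names(patients) <- ids

  labels <- dplyr::bind_rows(lapply(patients, function(p) {
    if (nrow(p$labels)) dplyr::mutate(p$labels, patient_id = p$patient_id,
                                      .before = 1L)
    else p$labels
  }))

  structure(
    list(patients = patients, labels = labels,
         groups = setNames(groups, ids), config = config),
    class = "actidel_cohort"
  )
}

#' @export
print.actidel_cohort <- function(x, ...) {
  nd <- sum(vapply(x$patients, function(p) p$n_days, 0L))
  ndel <- if (nrow(x$labels)) sum(x$labels$delirium) else 0L
  cat(sprintf("<actidel_cohort> %d patients, %d complete days (%.0f%% delirious)\n",
              length(x$patients), nd, if (nd) 100 * ndel / nd else 0))
  cat(sprintf("  groups: %d always / %d never / %d fluctuating\n",
              sum(x$groups == "always"), sum(x$groups == "never"),
              sum(x$groups == "fluctuating")))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

.draw_days <- function(spec, n) {
  if (is.numeric(spec) && length(spec) == 1L) {
    rep(as.integer(spec), n)
  } else {
    pmax(as.integer(spec$min),
         stats::rnbinom(n, size = spec$size, mu = spec$mu))
  }
}

# counts rounded to nearest integer; fluctuating patients take the remainder
.assign_groups <- function(n, frac_always, frac_never) {
  n_always <- round(frac_always * n)
  n_never <- round(frac_never * n)
  if (n_always + n_never > n) n_never <- n - n_always
  sample(rep(c("always", "never", "fluctuating"),
             c(n_always, n_never, n - n_always - n_never)))
}

# per-day delirium probability for fluctuating patients, chosen so the
# cohort-level day prevalence matches the configured target in expectation
.fluctuating_day_prob <- function(config) {
  frac_flux <- 1 - config$frac_always_delirious - config$frac_never_delirious
  if (frac_flux <= 0) return(0.5)
  p <- (config$delirium_prevalence_day - config$frac_always_delirious) /
    frac_flux
  min(max(p, 0.05), 0.95)
}

.minute_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60L + lt$min
}

.simulate_patient <- function(id, n_days, group, p_flux, config, origin) {
  n_days <- as.integer(n_days)
  enroll_min <- floor(runif(1, 8 * 60, 20 * 60))  # daytime enrollment
  enrollment <- origin + enroll_min * 60
  pre_len <- (.DAY_ANCHOR_MIN - enroll_min) %% 1440L
  anchor <- enrollment + pre_len * 60
  n_ep <- pre_len + n_days * 1440L

  delirium <- switch(group,
    always = rep(1L, n_days),
    never = rep(0L, n_days),
    fluctuating = {
      d <- stats::rbinom(n_days, 1L, p_flux)
      # a fluctuating patient with >= 2 days must show both label values
      if (n_days >= 2L && length(unique(d)) == 1L) d[n_days] <- 1L - d[n_days]
      d
    })

  if (n_ep == 0L) {
    return(.empty_patient(id, enrollment, anchor, config))
  }

  timestamp <- enrollment + (seq_len(n_ep) - 1L) * 60
  mod <- (enroll_min + seq_len(n_ep) - 1L) %% 1440L
  night <- mod >= 1320L | mod < 360L
  day_idx <- (seq_len(n_ep) - 1L - pre_len) %/% 1440L
  delir_ep <- if (n_days > 0L) delirium[pmax(day_idx, 0L) + 1L] else
    rep(0L, n_ep)

  # rest/wake Markov chain; delirium fragments night-time rest
  eff <- config$effect_size * delir_ep
  p_rw <- ifelse(night, pmin(0.015 * (1 + 2 * eff), 0.9), 0.10)
  p_wr <- ifelse(night, 0.25 / (1 + eff), 0.12)
  u <- runif(n_ep)
  wake <- logical(n_ep)
  prev <- !night[1L]
  for (t in seq_len(n_ep)) {
    prev <- if (prev) u[t] >= p_wr[t] else u[t] < p_rw[t]
    wake[t] <- prev
  }

  # patient-initiated activity; paretic arm attenuated
  amp_np <- rlnorm(n_ep, log(120), 0.6) * wake
  amp_p <- config$paresis_attenuation * rlnorm(n_ep, log(120), 0.6) * wake

  # care events: shared timing, unattenuated bursts in both arms
  care <- logical(n_ep)
  burst_np <- rlnorm(n_ep, log(400), 0.5)
  burst_p <- rlnorm(n_ep, log(400), 0.5)
  if (config$care_event_rate > 0) {
    interval <- 60 / config$care_event_rate
    k <- floor(n_ep / interval)
    if (k >= 1) {
      centers <- round(seq_len(k) * interval +
                         rnorm(k, 0, config$care_event_jitter_sd))
      for (c0 in centers) {
        idx <- c0:(c0 + 3L)
        care[idx[idx >= 1L & idx <= n_ep]] <- TRUE
      }
    }
  }
  pim_np <- round(amp_np + care * burst_np, 3)
  pim_p <- round(amp_p + care * burst_p, 3)

  # device-removal gaps (both arms off, values missing)
  removed <- logical(n_ep)
  if (n_days > 0L && config$gap_spec$prob_per_day > 0) {
    has_gap <- stats::rbinom(n_days, 1L, config$gap_spec$prob_per_day) == 1L
    dur <- as.integer(config$gap_spec$duration_min)
    starts <- floor(runif(n_days, 0, max(1, 1440 - dur)))
    for (d in which(has_gap)) {
      if (dur < 1L) next
      idx <- pre_len + (d - 1L) * 1440L + starts[d] + seq_len(dur)
      removed[idx[idx >= 1L & idx <= n_ep]] <- TRUE
    }
  }
  pim_np[removed] <- NA_real_
  pim_p[removed] <- NA_real_

  zcm_np <- .draw_zcm(pim_np)
  zcm_p <- .draw_zcm(pim_p)

  state <- ifelse(removed, "device_removed",
           ifelse(care, "care_event",
           ifelse(wake, "active_wake",
           ifelse(night, "sleep", "quiet_wake"))))

  assessed <- rep(1L, n_days)
  if (config$weekend_gaps && n_days > 0L) {
    wday <- as.POSIXlt(anchor + (seq_len(n_days) - 1L) * 86400,
                       tz = "UTC")$wday
    assessed[wday %in% c(0L, 6L)] <- 0L
  }
  ventilated <- .draw_ventilation(n_days)

  list(
    patient_id = id,
    enrollment = enrollment,
    anchor = anchor,
    n_days = n_days,
    excluded = FALSE,
    series = list(
      paretic = epoch_series(timestamp, pim_p, zcm_p, arm = "paretic"),
      non_paretic = epoch_series(timestamp, pim_np, zcm_np,
                                 arm = "non_paretic")
    ),
    states = state,
    labels = tibble::tibble(day_index = seq_len(n_days) - 1L,
                            delirium = delirium, assessed = assessed),
    daily = tibble::tibble(day_index = seq_len(n_days) - 1L,
                           ventilated = ventilated),
    clinical = .draw_clinical(id)
  )
}

.empty_patient <- function(id, enrollment, anchor, config) {
  empty <- epoch_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                        integer(), arm = "paretic")
  list(patient_id = id, enrollment = enrollment, anchor = anchor,
       n_days = 0L, excluded = TRUE,
       series = list(paretic = empty,
                     non_paretic = epoch_series(as.POSIXct(character(),
                                                           tz = "UTC"),
                                                numeric(), integer(),
                                                arm = "non_paretic")),
       states = character(),
       labels = tibble::tibble(day_index = integer(), delirium = integer(),
                               assessed = integer()),
       daily = tibble::tibble(day_index = integer(), ventilated = integer()),
       clinical = .draw_clinical(id))
}

# ZCM (movement frequency) modeled as Poisson with rate proportional to PIM
.draw_zcm <- function(pim) {
  lambda <- ifelse(is.na(pim), 0, 0.2 * pim)
  z <- rpois(length(pim), lambda)
  z[is.na(pim)] <- NA_integer_
  z
}

# static covariates drawn to match the cohort's published summary statistics;
# independent of the delirium trajectory by construction
.draw_clinical <- function(id) {
  lobar <- stats::rbinom(1L, 1L, 0.667)
  deep <- stats::rbinom(1L, 1L, 0.385)
  if (lobar == 0L && deep == 0L) lobar <- 1L
  tibble::tibble(
    patient_id = id,
    age = round(min(max(rnorm(1, 71.4, 12.2), 40), 95)),
    sex = stats::rbinom(1L, 1L, 0.54),
    nihss = as.integer(min(max(round(rnorm(1, 14.5, 4)), 5), 42)),
    ich_volume_cc = round(max(rnorm(1, 38.4, 24.1), 1), 1),
    lobar = lobar, deep = deep,
    ivh = stats::rbinom(1L, 1L, 0.539),
    ich_score = as.integer(min(max(round(rnorm(1, 2, 1)), 0), 6))
  )
}

.draw_ventilation <- function(n_days) {
  if (n_days == 0L) return(integer())
  if (stats::rbinom(1L, 1L, 0.205) == 0L) return(rep(0L, n_days))
  dur <- min(n_days, 1L + rpois(1L, 3))
  as.integer(seq_len(n_days) - 1L < dur)
}
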