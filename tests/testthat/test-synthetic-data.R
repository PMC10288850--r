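test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(delirium_prevalence_day = 1.2),
               "delirium_prevalence_day")
  expect_error(cohort_config(frac_always_delirious = 0.7,
                             frac_never_delirious = 0.5),
               "frac_always_delirious")
  expect_error(cohort_config(paresis_attenuation = -0.1),
               "paresis_attenuation")
  expect_error(cohort_config(gap_spec = list(prob_per_day = 0.1)),
               "gap_spec")
  expect_error(generate_cohort(list()), "cohort_config")
})

test_that("identical configurations reproduce identical cohorts", {
  cfg <- cohort_config(n_patients = 4, days_per_patient = 2, rng_seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("trajectory groups appear in the configured rounded counts", {
  cfg <- cohort_config(n_patients = 10, days_per_patient = 4,
                       frac_always_delirious = 0.3,
                       frac_never_delirious = 0.2, rng_seed = 7)
  coh <- generate_cohort(cfg)
  all_del <- vapply(coh$patients, function(p) all(p$labels$delirium == 1L),
                    TRUE)
  none_del <- vapply(coh$patients, function(p) all(p$labels$delirium == 0L),
                     TRUE)
  expect_equal(sum(all_del), 3L)
  expect_equal(sum(none_del), 2L)
  # fluctuating patients really fluctuate
  expect_equal(sum(!all_del & !none_del), 5L)
  # assignment is reproducible
  expect_identical(generate_cohort(cfg)$groups, coh$groups)
})

test_that("full paresis suppression with no care events zeroes the paretic arm", {
  coh <- generate_cohort(cohort_config(n_patients = 3, days_per_patient = 2,
                                       paresis_attenuation = 0,
                                       care_event_rate = 0, rng_seed = 5))
  for (p in coh$patients) {
    worn <- !is.na(p$series$paretic$pim)
    expect_true(all(p$series$paretic$pim[worn] == 0))
    # the non-paretic arm still moves
    expect_gt(sum(p$series$non_paretic$pim[!is.na(p$series$non_paretic$pim)]),
              0)
  }
})

test_that("paretic bursts co-occur with non-paretic care activity", {
  coh <- generate_cohort(cohort_config(n_patients = 4, days_per_patient = 3,
                                       paresis_attenuation = 0,
                                       care_event_rate = 1, rng_seed = 13))
  for (p in coh$patients) {
    par <- p$series$paretic$pim
    hot <- which(!is.na(par) & par > 0)
    expect_true(length(hot) > 0)
    expect_true(all(p$states[hot] == "care_event"))
    expect_true(all(p$series$non_paretic$pim[hot] > 0))
  }
})

test_that("device-removal gaps are missing in both arms, never zeros", {
  coh <- generate_cohort(cohort_config(n_patients = 5, days_per_patient = 4,
                                       gap_spec = list(prob_per_day = 1,
                                                       duration_min = 45),
                                       rng_seed = 21))
  p <- coh$patients[[1]]
  gone <- p$states == "device_removed"
  expect_gt(sum(gone), 0)
  expect_true(all(is.na(p$series$paretic$pim[gone])))
  expect_true(all(is.na(p$series$non_paretic$pim[gone])))
  expect_true(all(is.na(p$series$paretic$zcm[gone])))
})

test_that("zero effect size leaves night activity independent of the label", {
  coh <- generate_cohort(cohort_config(n_patients = 30, effect_size = 0,
                                       rng_seed = 31))
  ft <- build_feature_table(coh, featureset = "minutes_at_rest")
  # night rest fraction should not separate the label classes
  p <- t.test(rest_paretic_night ~ delirium, data = ft)$p.value
  expect_gt(p, 0.01)
})

test_that("night activity on delirious days rises with effect size", {
  night_mean <- function(effect) {
    coh <- generate_cohort(cohort_config(n_patients = 15,
                                         days_per_patient = 4,
                                         frac_always_delirious = 1,
                                         frac_never_delirious = 0,
                                         effect_size = effect,
                                         rng_seed = 77))
    vals <- unlist(lapply(coh$patients, function(p) {
      pd <- partition_days(p$series$paretic)
      pd$pim[pd$segment == "night"]
    }))
    mean(vals, na.rm = TRUE)
  }
  m <- vapply(c(0, 1, 2), night_mean, 0)
  expect_true(all(diff(m) >= 0))
})

test_that("day-level prevalence converges to the configured target", {
  coh <- generate_cohort(cohort_config(n_patients = 150, rng_seed = 55))
  prev <- mean(coh$labels$delirium)
  expect_lt(abs(prev - 0.71), 0.05)
})

test_that("enrollment-day truncation anchors the record at 13:00", {
  # enrolled 10:00 -> data begins 13:00 the same day
  r <- truncate_enrollment_day(make_record("10:00", 2 * 1440))
  expect_equal(format(r$series$paretic$timestamp[1], "%H:%M"), "13:00")
  expect_equal(as.Date(r$series$paretic$timestamp[1]),
               as.Date("2019-03-04"))
  expect_equal(r$n_days, 1L)
  expect_false(r$excluded)

  # enrolled 14:00 -> data begins 13:00 the next day
  r <- truncate_enrollment_day(make_record("14:00", 3 * 1440))
  expect_equal(format(r$series$paretic$timestamp[1], "%H:%M"), "13:00")
  expect_equal(as.Date(r$series$paretic$timestamp[1]),
               as.Date("2019-03-05"))

  # discharged before the first anchor -> excluded, zero days retained
  r <- truncate_enrollment_day(make_record("14:00", 120))
  expect_true(r$excluded)
  expect_equal(r$n_days, 0L)
  expect_equal(nrow(r$series$paretic), 0L)
})

test_that("truncate_cohort drops flagged patients and their labels", {
  coh <- small_cohort(n_patients = 4, days = 2, seed = 3)
  # force one patient to be too short to keep a complete day
  coh$patients[[2]]$series <- lapply(coh$patients[[2]]$series,
                                     function(s) s[1:100, ])
  coh$patients[[2]]$states <- coh$patients[[2]]$states[1:100]
  out <- truncate_cohort(coh)
  excl <- attr(out, "excluded")
  expect_equal(excl, names(coh$patients)[2])
  expect_false(excl %in% names(out$patients))
  expect_false(excl %in% out$labels$patient_id)
})
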