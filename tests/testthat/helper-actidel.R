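# Independent oracles and small fixtures, built in code.

# Exhaustive DTW oracle: walks every monotone boundary-matched warping path
# from (1,1) to (n,m), accumulating squared differences, and returns the
# square root of the minimal total. No memoization — this is path
# enumeration, independent of the dynamic-programming implementation.
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (i == n && j == m) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
  }
  walk(1, 1, 0)
  sqrt(best)
}

# brute-force recount of the rest fraction, loop-style
rest_oracle <- function(pim) {
  num <- 0L; den <- 0L
  for (v in pim) {
    if (!is.na(v)) {
      den <- den + 1L
      if (v == 0) num <- num + 1L
    }
  }
  if (den == 0L) NA_real_ else num / den
}

# independent re-implementation of the median + 10 SD outlier rule
outlier_oracle <- function(pim) {
  pres <- pim[!is.na(pim)]
  if (length(pres) < 2L) return(integer())
  s <- sd(pres)
  if (is.na(s) || s == 0) return(integer())
  thr <- median(pres) + 10 * s
  which(!is.na(pim) & pim >= thr)
}

# a small complete-day series starting at the 13:00 anchor
make_series <- function(n_days = 1L, pim = NULL,
                        start = as.POSIXct("2019-03-04 13:00", tz = "UTC"),
                        arm = "paretic") {
  n <- n_days * 1440L
  ts <- start + (seq_len(n) - 1L) * 60
  if (is.null(pim)) pim <- rep(0, n)
  epoch_series(ts, pim, ifelse(is.na(pim), NA_integer_, 0L), arm = arm)
}

# minimal patient record for truncation tests
make_record <- function(enroll_clock, n_minutes,
                        date = "2019-03-04", pim = NULL) {
  start <- as.POSIXct(paste(date, enroll_clock), tz = "UTC")
  ts <- start + (seq_len(n_minutes) - 1L) * 60
  if (is.null(pim)) pim <- rep(0, n_minutes)
  s <- epoch_series(ts, pim, rep(0L, n_minutes), arm = "paretic")
  ns <- epoch_series(ts, pim, rep(0L, n_minutes), arm = "non_paretic")
  list(patient_id = "T001", series = list(paretic = s, non_paretic = ns),
       states = rep("quiet_wake", n_minutes), n_days = NA_integer_,
       excluded = FALSE)
}

small_cohort <- function(n_patients = 6L, days = 3L, effect = 1,
                         seed = 11L, ...) {
  generate_cohort(cohort_config(n_patients = n_patients,
                                days_per_patient = days,
                                effect_size = effect, rng_seed = seed, ...))
}
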