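#' Proportion of epochs at rest
#'
#' The fraction of present epochs whose PIM is exactly zero within a
#' window. A zero epoch is a worn, motionless minute; missing epochs
#' (device off) are excluded from numerator and denominator.
#'
#' @param pim numeric vector of PIM values for one window (NAs allowed).
#' @return Fraction in `[0, 1]`, or `NA` when no epoch is present.
#' @export
#' @examples
#' minutes_at_rest(c(0, 5, 0, 0, 3))      # 0.6
#' minutes_at_rest(c(0, NA, 2, 0))        # 2/3
minutes_at_rest <- function(pim) {
  present <- !is.na(pim)
  if (!any(present)) return(NA_real_)
  sum(pim[present] == 0) / sum(present)
}

#' Select the within-patient DTW reference day
#'
#' For the `reference_day` scheme the control is the paretic arm on the
#' patient's first day labeled non-delirious; consistently delirious
#' patients without such a day fall back to their first day of data. For
#' the `non_paretic_arm` scheme the control is the same-day non-paretic
#' series, so the reference day equals the query day and no selection is
#' needed.
#'
#' @param labels integer 0/1 vector of delirium labels indexed by day
#'   (position 1 = day_index 0).
#' @param scheme `"reference_day"` or `"non_paretic_arm"`.
#' @param query_day 0-based day index of the query (used only by the
#'   `non_paretic_arm` scheme).
#' @return `list(scheme, reference_day_index, fallback_used)` with a
#'   0-based `reference_day_index`.
#' @export
#' @examples
#' select_reference(c(1, 1, 0, 1), "reference_day")  # day 2, no fallback
#' select_reference(c(1, 1, 1), "reference_day")     # day 0, fallback
select_reference <- function(labels,
                             scheme = c("reference_day", "non_paretic_arm"),
                             query_day = 0L) {
  scheme <- match.arg(scheme)
  if (scheme == "non_paretic_arm") {
    return(list(scheme = scheme,
                reference_day_index = as.integer(query_day),
                fallback_used = FALSE))
  }
  if (length(labels) == 0L) {
    stop("select_reference: patient has no labeled days", call. = FALSE)
  }
  nondel <- which(labels == 0L)
  if (length(nondel)) {
    list(scheme = scheme, reference_day_index = nondel[1L] - 1L,
         fallback_used = FALSE)
  } else {
    list(scheme = scheme, reference_day_index = 0L, fallback_used = TRUE)
  }
}

#' Remove extreme paretic-arm activity outliers
#'
#' Marks as missing every epoch with
#' `pim >= median(pim) + 10 * sd(pim)`, the median and SD computed once
#' over the patient's present paretic-arm epochs and frozen before removal,
#' so the filter is a single deterministic pass. Such extremes are presumed externally mediated
#' (e.g. nursing care). A constant series has zero spread and nothing is
#' removed.
#'
#' @param pim numeric vector of one patient's paretic-arm PIM values
#'   (all epochs, NAs allowed).
#' @return `list(pim, removed, threshold)`: the filtered vector (removed
#'   epochs set to `NA`), the removal count, and the threshold used
#'   (`NA` when undefined).
#' @export
filter_outliers <- function(pim) {
  present <- which(!is.na(pim))
  if (length(present) < 2L) {
    return(list(pim = pim, removed = 0L, threshold = NA_real_))
  }
  med <- stats::median(pim[present])
  s <- stats::sd(pim[present])
  if (is.na(s) || s == 0) {
    return(list(pim = pim, removed = 0L, threshold = NA_real_))
  }
  thr <- med + 10 * s
  hit <- present[pim[present] >= thr]
  pim[hit] <- NA_real_
  list(pim = pim, removed = length(hit), threshold = thr)
}

#' Build the day-level feature table for a cohort
#'
#' Runs the full feature-extraction pipeline: enrollment-day truncation,
#' optional paretic-arm outlier filtering, per-patient normalization,
#' partition into 13:00-anchored days and day parts, then one row per
#' (patient, assessed day) holding the selected feature blocks:
#'
#' * `clinical` — encoded covariates plus daily ventilation
#'   ([encode_clinical()]);
#' * `minutes_at_rest` — per-segment rest fractions for both arms
#'   (8 columns `rest_<arm>_<segment>`);
#' * `non_paretic_arm_dtw` — DTW of the paretic against the same-day
#'   non-paretic series, per segment (4 columns `dtw_nonparetic_<segment>`);
#' * `reference_day_dtw` — DTW of the paretic arm against the same segment
#'   of the reference day (4 columns `dtw_refday_<segment>`; see
#'   [select_reference()]).
#'
#' A day is retained only if every day-part has at least
#' `presence_floor` of its epochs present; missing features stay `NA`,
#' never zero. Missing epochs are dropped and the series compressed before
#' DTW. DTW distances are path-length normalized ([dtw_distance()]).
#'
#' @param cohort an `actidel_cohort`.
#' @param featureset character subset of
#'   `c("clinical", "minutes_at_rest", "non_paretic_arm_dtw",
#'   "reference_day_dtw")`.
#' @param normalization method passed to [normalize_series()].
#' @param presence_floor minimum present fraction per segment for a day to
#'   be retained.
#' @param outlier_filter apply [filter_outliers()] to each patient's
#'   paretic arm before normalization.
#' @param dtw_window optional Sakoe-Chiba band (epochs) for
#'   [dtw_distance()].
#' @param include_unassessed keep days with `assessed = 0` (default drops
#'   them; they carry no usable label).
#' @return A tibble with identifier columns `patient_id`, `day_index`, the
#'   label `delirium`, and the selected feature columns. Attributes:
#'   `featureset`, `references` (per-patient reference-day selections),
#'   `outliers_removed`, `feature_cols`.
#' @export
build_feature_table <- function(cohort,
                                featureset = c("clinical", "minutes_at_rest",
                                               "non_paretic_arm_dtw",
                                               "reference_day_dtw"),
                                normalization = "per_patient_max",
                                presence_floor = 0.8,
                                outlier_filter = FALSE,
                                dtw_window = NULL,
                                include_unassessed = FALSE) {
  known <- c("clinical", "minutes_at_rest", "non_paretic_arm_dtw",
             "reference_day_dtw")
  bad <- setdiff(featureset, known)
  if (length(bad)) {
    stop("unknown featureset token: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cohort <- truncate_cohort(cohort)

  n_outliers <- 0L
  references <- list()
  rows <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    if (p$n_days == 0L) next

    par <- p$series$paretic
    nonpar <- p$series$non_paretic
    if (outlier_filter) {
      filt <- filter_outliers(par$pim)
      par$pim <- filt$pim
      n_outliers <- n_outliers + filt$removed
    }
    par <- normalize_series(par, normalization)
    nonpar <- normalize_series(nonpar, normalization)
    par <- partition_days(par)
    nonpar <- partition_days(nonpar)

    refsel <- select_reference(p$labels$delirium, "reference_day")
    references[[pid]] <- refsel

    need_dtw_np <- "non_paretic_arm_dtw" %in% featureset
    need_dtw_rd <- "reference_day_dtw" %in% featureset
    need_rest <- "minutes_at_rest" %in% featureset

    for (d in unique(par$day_index)) {
      lab <- p$labels[p$labels$day_index == d, ]
      if (nrow(lab) == 0L) next
      if (!include_unassessed && lab$assessed == 0L) next

      pd <- par[par$day_index == d, ]
      npd <- nonpar[nonpar$day_index == d, ]
      if (!.day_retained(pd, presence_floor)) next

      row <- list(patient_id = pid, day_index = d,
                  delirium = lab$delirium)
      if (need_rest) {
        for (seg in .SEGMENTS) {
          row[[paste0("rest_paretic_", seg)]] <-
            minutes_at_rest(.seg_values(pd, seg))
          row[[paste0("rest_nonparetic_", seg)]] <-
            minutes_at_rest(.seg_values(npd, seg))
        }
      }
      if (need_dtw_np) {
        for (seg in .SEGMENTS) {
          row[[paste0("dtw_nonparetic_", seg)]] <-
            .safe_dtw(.seg_values(pd, seg), .seg_values(npd, seg),
                      dtw_window)
        }
      }
      if (need_dtw_rd) {
        rd <- par[par$day_index == refsel$reference_day_index, ]
        for (seg in .SEGMENTS) {
          row[[paste0("dtw_refday_", seg)]] <-
            .safe_dtw(.seg_values(pd, seg), .seg_values(rd, seg),
                      dtw_window)
        }
      }
      rows[[paste(pid, d)]] <- tibble::as_tibble(row)
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(patient_id = character(), day_index = integer(),
                   delirium = integer())
  if ("clinical" %in% featureset && nrow(out)) {
    clin <- encode_clinical(
      dplyr::bind_rows(lapply(cohort$patients, function(p) p$clinical)),
      dplyr::bind_rows(lapply(cohort$patients, function(p) {
        if (nrow(p$daily)) dplyr::mutate(p$daily, patient_id = p$patient_id,
                                         .before = 1L)
        else p$daily
      })))
    out <- dplyr::left_join(out, clin, by = c("patient_id", "day_index"))
  }

  attr(out, "featureset") <- featureset
  attr(out, "references") <- references
  attr(out, "outliers_removed") <- n_outliers
  attr(out, "feature_cols") <- setdiff(names(out),
                                       c("patient_id", "day_index",
                                         "delirium"))
  out
}

.seg_values <- function(day_rows, seg) {
  if (seg == "full_day") day_rows$pim else
    day_rows$pim[day_rows$segment == seg]
}

# day retained iff every day-part clears the presence floor
.day_retained <- function(day_rows, presence_floor) {
  if (nrow(day_rows) == 0L) return(FALSE)
  ok <- vapply(c("morning", "afternoon_evening", "night"), function(seg) {
    v <- day_rows$pim[day_rows$segment == seg]
    length(v) > 0L && mean(!is.na(v)) >= presence_floor
  }, TRUE)
  all(ok)
}

# missing epochs dropped and compressed before warping
.safe_dtw <- function(query, reference, window) {
  q <- query[!is.na(query)]
  r <- reference[!is.na(reference)]
  if (length(q) == 0L || length(r) == 0L) return(NA_real_)
  dtw_distance(q, r, window = window, normalize = TRUE)
}
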