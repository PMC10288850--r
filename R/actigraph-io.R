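#' Construct an epoch series
#'
#' An epoch series is one wrist's activity stream on a strict 1-minute grid:
#' a tibble with columns `timestamp` (POSIXct, minute resolution), `pim`
#' (non-negative real, area-under-curve activity per epoch) and `zcm`
#' (non-negative integer, threshold-crossing count per epoch). Missing
#' values mean the device was off; they are never zeros — a zero is a worn,
#' motionless epoch.
#'
#' @param timestamp POSIXct vector, strictly increasing, 60 s spacing.
#' @param pim numeric vector, `NA` or `>= 0`.
#' @param zcm integer-valued vector, `NA` or `>= 0`.
#' @param arm `"paretic"` or `"non_paretic"`.
#' @return A tibble of class `"epoch_series"` with an `arm` attribute.
#' @export
epoch_series <- function(timestamp, pim, zcm, arm = c("paretic", "non_paretic")) {
  arm <- match.arg(arm)
  n <- length(timestamp)
  if (length(pim) != n || length(zcm) != n) {
    stop("timestamp, pim and zcm must have equal length", call. = FALSE)
  }
  if (n > 1L) {
    d <- diff(as.numeric(timestamp))
    if (any(d <= 0)) {
      stop(sprintf("timestamps not strictly increasing at epoch %d",
                   which(d <= 0)[1L] + 1L), call. = FALSE)
    }
    if (any(d != 60)) {
      stop(sprintf("timestamps deviate from the 1-minute grid at epoch %d",
                   which(d != 60)[1L] + 1L), call. = FALSE)
    }
  }
  if (any(pim < 0, na.rm = TRUE)) {
    stop(sprintf("negative pim at epoch %d", which(pim < 0)[1L]),
         call. = FALSE)
  }
  if (any(zcm < 0, na.rm = TRUE) ||
      any(zcm != floor(zcm), na.rm = TRUE)) {
    stop(sprintf("zcm must be a non-negative integer (epoch %d)",
                 which(zcm < 0 | zcm != floor(zcm))[1L]), call. = FALSE)
  }
  out <- tibble::tibble(timestamp = timestamp, pim = as.numeric(pim),
                        zcm = as.integer(zcm))
  attr(out, "arm") <- arm
  class(out) <- c("epoch_series", class(out))
  out
}

.TS_FMT <- "%Y-%m-%dT%H:%M"

#' Read an epoch CSV into per-(patient, arm) series
#'
#' The epoch CSV dialect is UTF-8 with a header and columns `patient_id`,
#' `arm` (`paretic`/`non_paretic`), `timestamp` (ISO-8601, minute
#' resolution), `zcm` (integer or empty) and `pim` (float or empty). Empty
#' activity fields mean the device was off. Rows violating the 1-minute
#' grid, an unknown arm code or negative activity raise an error naming the
#' offending data row.
#'
#' @param path path to the CSV file.
#' @return A named list `patient_id -> list(paretic =, non_paretic =)` of
#'   [epoch_series()] (arms absent from the file are omitted).
#' @seealso [write_epoch_table()]
#' @export
read_epoch_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       arm = "character",
                                       timestamp = "character"))
  need <- c("patient_id", "arm", "timestamp", "zcm", "pim")
  if (!all(need %in% names(df))) {
    stop("epoch CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$.row <- seq_len(nrow(df)) + 1L  # file line number (header = line 1)
  bad_arm <- !df$arm %in% c("paretic", "non_paretic")
  if (any(bad_arm)) {
    stop(sprintf("unknown arm code %s at line %d",
                 df$arm[bad_arm][1L], df$.row[bad_arm][1L]), call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC", format = .TS_FMT)
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp at line %d",
                 df$.row[is.na(ts)][1L]), call. = FALSE)
  }
  if (any(df$pim < 0, na.rm = TRUE)) {
    stop(sprintf("negative pim at line %d",
                 df$.row[which(df$pim < 0)[1L]]), call. = FALSE)
  }
  if (any(df$zcm < 0, na.rm = TRUE)) {
    stop(sprintf("negative zcm at line %d",
                 df$.row[which(df$zcm < 0)[1L]]), call. = FALSE)
  }
  df$timestamp <- ts

  out <- list()
  for (pid in unique(df$patient_id)) {
    arms <- list()
    for (a in intersect(c("paretic", "non_paretic"),
                        unique(df$arm[df$patient_id == pid]))) {
      sub <- df[df$patient_id == pid & df$arm == a, ]
      d <- diff(as.numeric(sub$timestamp))
      if (any(d <= 0)) {
        stop(sprintf("non-monotone timestamps for %s/%s at line %d",
                     pid, a, sub$.row[which(d <= 0)[1L] + 1L]),
             call. = FALSE)
      }
      if (any(d != 60)) {
        stop(sprintf("1-minute grid violated for %s/%s at line %d",
                     pid, a, sub$.row[which(d != 60)[1L] + 1L]),
             call. = FALSE)
      }
      arms[[a]] <- epoch_series(sub$timestamp, sub$pim, sub$zcm, arm = a)
    }
    out[[pid]] <- arms
  }
  out
}

#' Write epoch series to the epoch CSV dialect
#'
#' @param series_by_patient a named list as returned by [read_epoch_table()],
#'   or a full `actidel_cohort` (its series are written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(series_by_patient, path) {
  if (inherits(series_by_patient, "actidel_cohort")) {
    series_by_patient <- lapply(series_by_patient$patients,
                                function(p) p$series)
  }
  rows <- list()
  for (pid in names(series_by_patient)) {
    for (a in names(series_by_patient[[pid]])) {
      s <- series_by_patient[[pid]][[a]]
      rows[[paste(pid, a)]] <- data.frame(
        patient_id = pid, arm = a,
        timestamp = format(s$timestamp, .TS_FMT, tz = "UTC"),
        zcm = s$zcm, pim = s$pim, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read day-level delirium labels
#'
#' Columns: `patient_id`, `day_index` (0-based complete analysis day),
#' `delirium` (0/1), `assessed` (0/1; 0 marks weekend/holiday days with no
#' rating).
#' @param path CSV path.
#' @return A tibble.
#' @export
read_labels_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  need <- c("patient_id", "day_index", "delirium", "assessed")
  if (!all(need %in% names(df))) {
    stop("labels CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$delirium %in% 0:1) || !all(df$assessed %in% 0:1)) {
    stop("delirium and assessed must be 0/1", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Locate the first 13:00 analysis-day anchor at or after a time point
#' @param t a POSIXct scalar.
#' @return POSIXct scalar.
#' @keywords internal
first_anchor <- function(t) {
  m <- .minute_of_day(t)
  t + ((.DAY_ANCHOR_MIN - m) %% 1440L) * 60
}

#' Assign epochs to complete analysis days and day-part segments
#'
#' Analysis days are anchored at 13:00 and run to the next 13:00 (half-open).
#' Within a day the chronological day parts are afternoon/evening
#' `[13:00, 22:00)`, night `[22:00, 06:00)` and morning `[06:00, 13:00)`;
#' every epoch belongs to exactly one. Only complete 24-h windows are
#' returned: epochs before the first anchor or after the last complete day
#' are dropped.
#'
#' @param series an [epoch_series()] (or any tibble with a `timestamp`
#'   column on the 1-minute grid).
#' @return The series restricted to complete days, with added columns
#'   `day_index` (0-based) and `segment`
#'   (`morning` / `afternoon_evening` / `night`). Zero-row tibble when no
#'   complete day exists.
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2019-03-04 13:00", tz = "UTC"), by = 60,
#'           length.out = 2880)
#' s <- epoch_series(ts, rep(0, 2880), rep(0L, 2880))
#' table(partition_days(s)$day_index)
partition_days <- function(series) {
  out <- series
  out$day_index <- NA_integer_
  out$segment <- NA_character_
  if (nrow(series) == 0L) return(out[0L, ])

  anchor <- first_anchor(series$timestamp[1L])
  off <- as.integer(round(as.numeric(series$timestamp - anchor,
                                     units = "mins")))
  n_days <- max(0L, (max(off) + 1L) %/% 1440L)
  keep <- off >= 0L & off < n_days * 1440L
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  off <- off[keep]
  out$day_index <- off %/% 1440L
  m <- .minute_of_day(out$timestamp)
  out$segment <- ifelse(m >= .SEG_MORNING[1L] & m < .SEG_MORNING[2L],
                        "morning",
                 ifelse(m >= .SEG_AFTEVE[1L] & m < .SEG_AFTEVE[2L],
                        "afternoon_evening", "night"))
  out
}

#' Normalize an epoch series per patient and arm
#'
#' Scaling parameters are computed from the series' own present values, so
#' normalization is per patient per arm by construction. Every method maps
#' zero activity to zero and preserves missingness, which keeps the
#' minutes-at-rest feature invariant to normalization.
#'
#' @param series an [epoch_series()].
#' @param method `"per_patient_max"` (divide by the maximum present value),
#'   `"per_patient_z_nonneg"` (divide by the SD of present values — scaling
#'   without centering, so zeros and non-negativity survive), or `"none"`.
#' @param channels which channels to scale.
#' @return The rescaled series; the scaling parameters are recorded in the
#'   `normalization` attribute.
#' @export
normalize_series <- function(series,
                             method = c("per_patient_max",
                                        "per_patient_z_nonneg", "none"),
                             channels = c("pim", "zcm")) {
  method <- match.arg(method)
  if (all(is.na(series$pim)) && all(is.na(series$zcm))) {
    stop("cannot normalize an all-missing series", call. = FALSE)
  }
  prov <- list(method = method)
  if (method != "none") {
    for (ch in channels) {
      x <- series[[ch]]
      scale <- switch(method,
        per_patient_max = max(x, na.rm = TRUE),
        per_patient_z_nonneg = stats::sd(x, na.rm = TRUE))
      if (is.na(scale) || scale == 0) scale <- 1  # degenerate: leave unchanged
      series[[ch]] <- as.numeric(x) / scale
      prov[[ch]] <- scale
    }
  }
  attr(series, "normalization") <- prov
  series
}
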