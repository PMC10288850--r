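#' Dynamic time warping distance between two activity sequences
#'
#' Computes the minimal Euclidean distance between two sequences over all
#' monotone, boundary-matched warping paths: local cost is the squared
#' difference, costs accumulate along the path with
#' diagonal/vertical/horizontal steps, and the square root of the minimal
#' accumulated cost is returned. The distance is 0 exactly when a
#' zero-cost alignment exists (in particular for elementwise-equal
#' sequences), and is symmetric in its arguments.
#'
#' Aligning a day-part of the paretic arm against a within-patient control
#' — the same-day non-paretic arm, or the same day part of a baseline day —
#' cancels activity that is shared by both streams, such as care routines
#' recurring at slightly varying times.
#'
#' @param query,reference numeric vectors, non-empty, no `NA` (drop missing
#'   epochs first; see [build_feature_table()]).
#' @param window optional Sakoe-Chiba band half-width (epochs): warping is
#'   restricted to `|i - j| <= max(window, |n - m|)`. `NULL` = unconstrained.
#' @param normalize if `TRUE`, divide the distance by the step count of the
#'   optimal warping path, making segments with different missing-data
#'   loads comparable.
#' @return A single non-negative number.
#' @export
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: a zero-cost alignment exists
#' dtw_distance(c(0, 0, 1), c(1, 0, 0))
dtw_distance <- function(query, reference, window = NULL, normalize = FALSE) {
  if (length(query) == 0L || length(reference) == 0L) {
    stop("dtw_distance: sequences must be non-empty", call. = FALSE)
  }
  if (anyNA(query) || anyNA(reference)) {
    stop("dtw_distance: missing values must be removed first", call. = FALSE)
  }
  w <- if (is.null(window)) NA_integer_ else as.integer(window)
  res <- .Call(c_dtw, as.numeric(query), as.numeric(reference), w)
  if (normalize) res[1L] / res[2L] else res[1L]
}
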