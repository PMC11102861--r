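#' Unity-based normalization of an assay matrix
#'
#' Divides every entry by the global maximum over the whole species-by-time
#' matrix, so values lie in `[0, 1]` with max exactly 1. This assay-wide
#' normalization removes the arbitrary fluorescence scale and is the form in
#' which intensities enter rate fitting. Idempotent and invariant to
#' positive rescaling of the input.
#'
#' @param tc A raw time-course tibble with nonnegative entries, not all zero.
#' @return The normalized time-course tibble.
#' @export
normalize_assay <- function(tc) {
  validate_time_course(tc)
  vals <- tc_values(tc)
  m <- max(vals)
  if (m <= 0) abort("Cannot normalize an all-zero matrix.")
  time_course(vals / m, tc_times(tc), positions = tc$position)
}

#' Column-specific unity-based normalization
#'
#' Divides each time-point column by its own maximum, highlighting the most
#' abundant species at every time. Used only for heatmap visualization —
#' never as a fitting target, since it destroys relative abundance across
#' time points. All-zero columns are left at zero with a warning.
#'
#' @inheritParams normalize_assay
#' @return The column-normalized time-course tibble.
#' @export
normalize_columns <- function(tc) {
  validate_time_course(tc)
  vals <- tc_values(tc)
  maxes <- apply(vals, 2, max)
  if (any(maxes == 0)) {
    warn("Zero column(s) left at zero during column normalization.")
  }
  scale <- ifelse(maxes > 0, maxes, 1)
  time_course(sweep(vals, 2, scale, "/"), tc_times(tc), positions = tc$position)
}
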