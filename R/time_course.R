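#' Species-by-time intensity tables
#'
#' The central data structure of the package is an ordinary tibble holding
#' one row per gel species and one column per reaction time: the first
#' column, `position`, is the species index `s = 1..N+1` (1 = intact
#' substrate, `N + 1` = tailless body) and every remaining column is headed
#' by its reaction time in minutes. This is also the on-disk TSV dialect
#' ([read_time_course()]).
#'
#' @param values Numeric matrix, species x time, nonnegative.
#' @param times Reaction times in minutes, strictly increasing, one per
#'   column of `values`.
#' @param positions Species indices; defaults to `1:nrow(values)`.
#' @return A tibble with columns `position`, then one per time.
#' @examples
#' tc <- time_course(matrix(c(1, 0, 0.5, 0.5), nrow = 2), times = c(0, 4))
#' tc_times(tc)
#' tc_values(tc)
#' @export
time_course <- function(values, times, positions = NULL) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (ncol(values) != length(times)) {
    abort("`values` must have one column per element of `times`.")
  }
  check_times(times)
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("Abundances must be finite and nonnegative.")
  }
  positions <- positions %||% seq_len(nrow(values))
  out <- as_tibble(values, .name_repair = ~ format_times(times))
  dplyr::bind_cols(tibble(position = as.integer(positions)), out)
}

format_times <- function(times) {
  format(times, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

check_times <- function(times) {
  if (length(times) == 0 || any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort("`times` must be finite and strictly increasing.")
  }
  invisible(times)
}

#' @rdname time_course
#' @param tc A time-course tibble.
#' @export
tc_times <- function(tc) {
  validate_time_course(tc)
  as.numeric(setdiff(names(tc), "position"))
}

#' @rdname time_course
#' @export
tc_values <- function(tc) {
  validate_time_course(tc)
  m <- as.matrix(tc[setdiff(names(tc), "position")])
  rownames(m) <- tc$position
  m
}

validate_time_course <- function(tc) {
  if (!is.data.frame(tc) || !"position" %in% names(tc)) {
    abort("A time course must be a data frame with a `position` column.")
  }
  tcols <- setdiff(names(tc), "position")
  if (length(tcols) == 0) abort("A time course needs at least one time column.")
  times <- suppressWarnings(as.numeric(tcols))
  if (any(is.na(times)) || any(diff(times) <= 0)) {
    abort("Time columns must be numeric headers in strictly increasing order.")
  }
  if (anyDuplicated(tc$position)) abort("Duplicate species positions.")
  vals <- as.matrix(tc[tcols])
  if (any(!is.finite(vals))) abort("Non-finite abundance values.")
  if (any(vals < 0)) abort("Negative abundance values.")
  invisible(tc)
}

#' Audit conservation of total RNA across time points
#'
#' In a closed deadenylation reaction the summed abundance over all species
#' is constant; a drifting lane total indicates loading or quantification
#' artefacts (or, for simulated data, integrator error). Totals are compared
#' against the first time point.
#'
#' @param tc Raw (un-normalized) time-course tibble.
#' @param tol Maximum tolerated relative deviation from the first total.
#' @return A tibble with `time`, `total` and logical `flagged`.
#' @export
mass_balance <- function(tc, tol = 1e-6) {
  validate_time_course(tc)
  vals <- tc_values(tc)
  totals <- colSums(vals)
  if (all(totals == 0)) abort("All-zero matrix: no mass to balance.")
  ref <- totals[[1]]
  if (ref == 0) abort("Zero total at the first time point; cannot form a reference.")
  tibble(
    time = tc_times(tc),
    total = unname(totals),
    flagged = unname(abs(totals - ref) / ref > tol)
  )
}

#' Read and write time-course tables
#'
#' Tab-separated files with a `position` column followed by columns headed
#' by reaction time in minutes; the round trip through
#' `write_time_course()` / `read_time_course()` is lossless.
#'
#' @param path File path.
#' @return `read_time_course()` returns a time-course tibble;
#'   `write_time_course()` returns `tc` invisibly.
#' @export
read_time_course <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort("Empty or malformed time-course file (need `position` + time columns).")
  }
  if (names(raw)[1] != "position") {
    abort("First column of a time-course file must be named `position`.")
  }
  for (j in seq_along(raw)) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      abort(sprintf(
        "Non-numeric value %s at row %d, column `%s`.",
        dQuote(raw[[j]][i]), i, names(raw)[j]
      ))
    }
    raw[[j]] <- num
  }
  tc <- as_tibble(raw)
  tc$position <- as.integer(tc$position)
  validate_time_course(tc)
  tc
}

#' @rdname read_time_course
#' @param tc A time-course tibble.
#' @export
write_time_course <- function(tc, path) {
  validate_time_course(tc)
  utils::write.table(tc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tc)
}

#' Pivot a time course to long format
#'
#' Convenience for plotting and dplyr-style summaries.
#'
#' @param tc A time-course tibble.
#' @return A tibble with `position`, `time`, `abundance`.
#' @export
tc_longer <- function(tc) {
  validate_time_course(tc)
  tidyr::pivot_longer(tc, -"position",
    names_to = "time", values_to = "abundance",
    names_transform = as.numeric
  )
}
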