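#' Gel-lane densitometry profiles
#'
#' A lane profile is the 1D intensity trace along the migration (vertical)
#' axis of one gel lane, with one value per pixel row, already summed across
#' the lane width. `lane_profile()` wraps a numeric vector;
#' `collapse_lane_image()` row-sums a rectangular pixel region (rows =
#' migration axis), which is all the image handling this package does —
#' upstream image I/O stays with dedicated tools.
#'
#' @param intensity Nonnegative intensity, one value per pixel row.
#' @return A tibble with columns `row` and `intensity`.
#' @export
lane_profile <- function(intensity) {
  intensity <- as.numeric(intensity)
  if (length(intensity) < 3 || any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("`intensity` must be a nonnegative vector with at least 3 rows.")
  }
  tibble(row = seq_along(intensity), intensity = intensity)
}

#' @rdname lane_profile
#' @param pixels Numeric matrix; rows follow the migration axis.
#' @export
collapse_lane_image <- function(pixels) {
  lane_profile(rowSums(as.matrix(pixels)))
}

as_profile_intensity <- function(profile) {
  if (is.data.frame(profile)) {
    if (!all(c("row", "intensity") %in% names(profile))) {
      abort("A lane profile needs `row` and `intensity` columns.")
    }
    profile$intensity[order(profile$row)]
  } else {
    as.numeric(profile)
  }
}

#' Segment a lane profile into per-species bands
#'
#' Separator rows between adjacent RNA species are located as local maxima
#' of the discrete second difference of the (optionally smoothed) profile —
#' the points of strongest upward curvature, i.e. the intensity valleys
#' between bands. The `expected_bands` strongest separators are kept; when
#' candidates tie at the cutoff, the combination giving the most even
#' segment widths wins (gel ladders have near-uniform single-nucleotide
#' spacing). Segmentation is invariant to adding a constant offset to the
#' profile. Manual curation of boundaries is expressed as a reproducible
#' `overrides` table instead of ad hoc edits.
#'
#' @param profile A [lane_profile()] tibble (or bare numeric vector).
#' @param expected_bands Number of species bands the lane must contain.
#' @param smooth Width (rows) of the moving-average smoother applied before
#'   differencing; `1` disables smoothing.
#' @param overrides Optional named numeric vector or two-column data frame
#'   (`boundary`, `row`) replacing specific internal boundaries (boundary
#'   `j` separates band `j` from band `j + 1`).
#' @return A tibble with one row per band: `band` (= species index, in
#'   migration order), `start_row`, `end_row`.
#' @export
find_band_boundaries <- function(profile, expected_bands, smooth = 3,
                                 overrides = NULL) {
  y <- as_profile_intensity(profile)
  n <- length(y)
  if (expected_bands < 1) abort("`expected_bands` must be >= 1.")
  if (n <= 3 * expected_bands) {
    abort("Profile too short for the expected number of bands.")
  }
  ys <- smooth_profile(y, smooth)
  if (diff(range(ys)) <= 1e-12 * max(abs(ys), 1)) {
    abort("Flat profile: no band structure to segment.")
  }
  d2 <- c(NA, diff(ys, differences = 2), NA) # d2[i] aligned to row i

  # separators are the intensity minima between bands; the second
  # difference (largest where upward curvature peaks) ranks them
  interior <- 2:(n - 1)
  cand <- interior[ys[interior] <= ys[interior - 1] & ys[interior] <= ys[interior + 1]]
  cand <- collapse_runs(cand)

  needed <- expected_bands - 1L
  if (length(cand) < needed) {
    abort(sprintf(
      "Found only %d candidate separator(s) but %d needed (flat or under-resolved profile).",
      length(cand), needed
    ))
  }
  boundaries <- if (needed == 0) integer(0) else {
    pick_separators(cand, d2[cand], needed, n)
  }
  boundaries <- apply_overrides(boundaries, overrides, n)

  seg <- tibble(
    band = seq_len(expected_bands),
    start_row = c(1L, boundaries + 1L),
    end_row = c(boundaries, n)
  )
  if (any(seg$start_row > seg$end_row)) {
    abort("Segmentation produced an empty band; adjust overrides or smoothing.")
  }
  seg
}

smooth_profile <- function(y, width) {
  if (width <= 1) return(y)
  sm <- as.numeric(stats::filter(y, rep(1 / width, width), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

# collapse runs of consecutive indices (second-difference plateaus) to centers
collapse_runs <- function(idx) {
  if (length(idx) == 0) return(idx)
  grp <- cumsum(c(1, diff(idx) != 1))
  as.integer(round(tapply(idx, grp, function(g) g[ceiling(length(g) / 2)])))
}

# keep the `needed` highest-curvature separators; break score ties at the
# cutoff in favour of the most even segment widths
pick_separators <- function(cand, score, needed, n) {
  ord <- order(score, decreasing = TRUE)
  cutoff <- score[ord[needed]]
  eps <- 1e-9 * max(abs(score), 1)
  sure <- cand[score > cutoff + eps]
  tied <- cand[abs(score - cutoff) <= eps]
  k <- needed - length(sure)
  if (k > 0 && length(tied) > k && choose(length(tied), k) <= 500) {
    combos <- utils::combn(tied, k, simplify = FALSE)
    spread <- map_dbl(combos, function(ch) {
      sd(diff(c(0L, sort(c(sure, ch)), n)))
    })
    sure <- c(sure, combos[[which.min(spread)]])
  } else if (k > 0) {
    sure <- c(sure, tied[seq_len(k)])
  }
  sort(as.integer(sure))
}

apply_overrides <- function(boundaries, overrides, n) {
  if (is.null(overrides)) return(boundaries)
  if (is.data.frame(overrides)) {
    idx <- as.integer(overrides$boundary)
    rows <- as.integer(overrides$row)
  } else {
    idx <- as.integer(names(overrides))
    rows <- as.integer(overrides)
  }
  if (anyNA(idx) || any(idx < 1 | idx > length(boundaries))) {
    abort("Override boundary indices must address existing boundaries.")
  }
  boundaries[idx] <- rows
  boundaries <- sort(boundaries)
  if (any(boundaries < 1 | boundaries >= n) || anyDuplicated(boundaries)) {
    abort("Overridden boundaries must be distinct rows inside the profile.")
  }
  boundaries
}

#' Quantify band intensities within a segmentation
#'
#' Each species' intensity is the maximum profile value inside its segment
#' (peak height, not integrated area — matching how the assays were
#' quantified), reported in species order.
#'
#' @param profile A [lane_profile()] tibble (or bare numeric vector).
#' @param segmentation Output of [find_band_boundaries()].
#' @return A tibble with `band` and `intensity`.
#' @export
quantify_bands <- function(profile, segmentation) {
  y <- as_profile_intensity(profile)
  if (!all(c("band", "start_row", "end_row") %in% names(segmentation))) {
    abort("`segmentation` must come from find_band_boundaries().")
  }
  if (any(segmentation$start_row > segmentation$end_row) ||
    any(segmentation$start_row < 1) || any(segmentation$end_row > length(y))) {
    abort("Segmentation contains an empty or out-of-range band.")
  }
  segmentation |>
    dplyr::rowwise() |>
    mutate(intensity = max(y[.data$start_row:.data$end_row])) |>
    ungroup() |>
    select("band", "intensity")
}

#' Quantify a set of lanes into a species-by-time matrix
#'
#' Segments the gel once — on a reference profile in which every species is
#' visible — and applies that segmentation to each time-point lane with
#' [quantify_bands()], assembling the raw species-by-time intensity matrix
#' ready for [normalize_assay()] and [estimate_rates()]. By default the
#' reference is the element-wise sum of all assay lanes: every species
#' transits the reaction at some time, so the summed lane shows the full
#' ladder even though no single lane does (the gel-wide analogue of
#' marker-anchored boundaries; lanes of one gel share migration rows). A
#' lane named `"marker"` is excluded from the matrix.
#'
#' @param lanes Named list of lane profiles; names are reaction times in
#'   minutes (as produced by [render_lanes()]).
#' @param expected_bands Number of species (`N + 1`).
#' @param reference Optional lane profile to segment instead of the lane
#'   sum (e.g. a full ladder lane).
#' @inheritParams find_band_boundaries
#' @return A raw time-course tibble.
#' @export
quantify_lanes <- function(lanes, expected_bands, reference = NULL,
                           smooth = 3, overrides = NULL) {
  lanes <- lanes[names(lanes) != "marker"]
  times <- suppressWarnings(as.numeric(names(lanes)))
  if (length(lanes) == 0 || anyNA(times)) {
    abort("`lanes` must be a list named by reaction time in minutes.")
  }
  traces <- map(lanes, as_profile_intensity)
  if (length(unique(lengths(traces))) != 1) {
    abort("All lanes of one gel must share the same migration axis length.")
  }
  reference <- reference %||% lane_profile(Reduce(`+`, traces))
  seg <- find_band_boundaries(reference, expected_bands,
                              smooth = smooth, overrides = overrides)
  vals <- vapply(traces, function(y) quantify_bands(y, seg)$intensity,
                 numeric(expected_bands))
  ord <- order(times)
  time_course(vals[, ord, drop = FALSE], times[ord])
}
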