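#' Per-position removal times
#'
#' The reciprocal of a removal rate is the reaction time for that single
#' hydrolysis event (`z_p = 1 / lambda_p`, minutes). Positions with a zero
#' rate have no defined removal time and are marked unavailable.
#'
#' @param rates A rate tibble (`position`, `lambda`) or numeric vector.
#' @return A tibble with `position`, `z` and logical `available`.
#' @export
removal_times <- function(rates) {
  lambda <- as_rates(rates)
  if (all(lambda == 0)) abort("All rates are zero; removal times undefined.")
  tibble(
    position = seq_along(lambda),
    z = ifelse(lambda > 0, 1 / lambda, NA_real_),
    available = lambda > 0
  )
}

z_at <- function(z_tbl, positions, what) {
  idx <- match(positions, z_tbl$position)
  if (anyNA(idx) || anyNA(z_tbl$z[idx])) {
    abort(sprintf(
      "%s has no finite removal time at tail position(s) %s.",
      what, paste(positions[is.na(idx) | is.na(z_tbl$z[idx])], collapse = ", ")
    ))
  }
  z_tbl$z[idx]
}

#' Construct the no-stalling baseline for a non-A residue
#'
#' The enzyme slows down gradually even on pure poly(A), so the removal
#' times around a non-A residue cannot be compared to a constant. The
#' baseline assumes the gradual slowdown in the mixed-tail experiment is
#' proportional to that in the matched pure-A control:
#' `b = (z(-3) - z(+2)) / (zA(-3) - zA(+2))` scales the control's slowdown
#' into the mixed experiment, `epsilon(i) = b * (zA(-3) - zA(i))` is the
#' expected slowdown at offset `i`, and `z0(i) = z(-3) - epsilon(i)` is the
#' removal time had there been no stalling. Offsets are relative to the
#' non-A residue's tail position `r` (`z(i) = z[r + i]`; offset 0 is the
#' residue itself, -1 the residue 3' of it). The calibration offsets
#' (default -3 and +2) must lie outside the stalled window `{-2, -1, 0}`.
#'
#' @param z_mixed [removal_times()] tibble for the mixed-tail fit.
#' @param z_control Matched pure-poly(A) control [removal_times()] tibble.
#' @param anchor Tail position `r` of the non-A residue (3'-anchored).
#' @param calibration Two offsets used to estimate `b` (default `c(-3, 2)`).
#' @param substrate Optional [tail_substrate()]; if supplied, `anchor` must
#'   be one of its non-A positions.
#' @return A tibble with one row per offset in `{-2, -1, 0}`: `offset`,
#'   `position`, `z`, `z_control`, `epsilon`, `z_null`, and the scaling
#'   constant `b` (repeated).
#' @export
no_stall_baseline <- function(z_mixed, z_control, anchor,
                              calibration = c(-3, 2), substrate = NULL) {
  if (length(calibration) != 2 || any(calibration %in% (-2:0))) {
    abort("`calibration` must be two offsets outside the stalled window {-2, -1, 0}.")
  }
  if (!is.null(substrate) && !(anchor %in% non_a_positions(substrate))) {
    abort(sprintf("Anchor %d is not a non-A residue of %s.", anchor, substrate$name))
  }
  offs <- c(-2L, -1L, 0L)
  z_cal <- z_at(z_mixed, anchor + calibration, "Mixed profile")
  zA_cal <- z_at(z_control, anchor + calibration, "Control profile")
  z <- z_at(z_mixed, anchor + offs, "Mixed profile")
  zA <- z_at(z_control, anchor + offs, "Control profile")
  zA_ref <- z_at(z_control, anchor + calibration[1], "Control profile")
  denom <- zA_cal[1] - zA_cal[2]
  tol <- 1e-9 * max(abs(c(zA_cal, zA)), 1)
  if (abs(denom) < tol) {
    # a flat control shows no gradual slowdown: epsilon(i) = 0 for any b
    if (max(abs(zA_ref - zA)) < tol) {
      b <- 1
    } else {
      abort("Control removal times are equal at the calibration offsets; choose different anchors.")
    }
  } else {
    b <- (z_cal[1] - z_cal[2]) / denom
  }
  eps <- b * (zA_ref - zA)
  tibble(
    offset = offs,
    position = anchor + offs,
    z = z,
    z_control = zA,
    epsilon = eps,
    z_null = z_cal[1] - eps,
    b = b
  )
}

#' Stalling effect size (adenosine-equivalents)
#'
#' The stalling effect of a single non-A residue spans three positions
#' (offsets -2, -1, 0); assuming independent changes at each, the effect
#' size is `zeta = z(-2)/z0(-2) + z(-1)/z0(-1) + z(0)/z0(0) - 2`, the number
#' of adenosines whose removal takes as long as traversing the residue's
#' influence zone. With no stalling (`z = z0` everywhere) `zeta = 1`: the
#' residue costs exactly one ordinary nucleotide.
#'
#' @param baseline Output of [no_stall_baseline()], or any data frame with
#'   positive `z` and `z_null` columns for the three offsets.
#' @return The scalar effect size `zeta`.
#' @examples
#' stalling_effect(data.frame(z = c(2, 6, 4), z_null = c(2, 2, 2))) # 1+3+2-2
#' @export
stalling_effect <- function(baseline) {
  if (!is.data.frame(baseline) || !all(c("z", "z_null") %in% names(baseline))) {
    abort("`baseline` must have `z` and `z_null` columns (see no_stall_baseline()).")
  }
  if (nrow(baseline) != 3) abort("Expected exactly the three offsets -2, -1, 0.")
  if (any(baseline$z_null <= 0) || any(baseline$z <= 0)) {
    abort("Removal times and baselines must be positive.")
  }
  sum(baseline$z / baseline$z_null) - 2
}

#' Assess stalling for every non-A residue of a substrate
#'
#' Convenience driver chaining [removal_times()], [no_stall_baseline()] and
#' [stalling_effect()] for each non-A residue, each anchored at its own
#' tail position with the control read at the same absolute positions.
#'
#' @param rates_mixed Fitted rate tibble for the mixed-tail assay.
#' @param rates_control Fitted rate tibble for the matched pure-A control.
#' @param substrate The mixed-tail [tail_substrate()].
#' @param calibration Calibration offsets, as in [no_stall_baseline()].
#' @return A tibble with one row per residue: `anchor`, `residue`, `b`,
#'   `zeta`.
#' @export
assess_stalling <- function(rates_mixed, rates_control, substrate,
                            calibration = c(-3, 2)) {
  anchors <- non_a_positions(substrate)
  if (length(anchors) == 0) abort("Substrate has no non-A residues to assess.")
  z_m <- removal_times(rates_mixed)
  z_c <- removal_times(rates_control)
  purrr::map_dfr(anchors, function(r) {
    base <- no_stall_baseline(z_m, z_c, r, calibration = calibration,
                              substrate = substrate)
    tibble(
      anchor = r,
      residue = residue(substrate, r),
      b = base$b[1],
      zeta = stalling_effect(base)
    )
  })
}

#' Summarise stalling effects across replicate assays
#'
#' Replicate gels are fit independently; their effect sizes are aggregated
#' per residue type (and any further grouping, e.g. complex variant or
#' anchor) as mean and standard error of the mean (`sd / sqrt(n)`; `NA`
#' for a single replicate).
#'
#' @param zeta_tbl Data frame with a `zeta` column, one row per replicate.
#' @param ... Grouping columns (tidy-select), e.g. `residue, variant`.
#' @return A tibble with `mean_zeta`, `sem`, `n` per group.
#' @export
aggregate_replicates <- function(zeta_tbl, ...) {
  if (!is.data.frame(zeta_tbl) || !"zeta" %in% names(zeta_tbl) ||
      nrow(zeta_tbl) == 0) {
    abort("`zeta_tbl` must be a non-empty data frame with a `zeta` column.")
  }
  zeta_tbl |>
    group_by(...) |>
    summarise(
      mean_zeta = mean(.data$zeta),
      sem = if (n() >= 2) sd(.data$zeta) / sqrt(n()) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}

#' Effective pure-poly(A) length of a designed mixed tail
#'
#' Each non-A residue is worth its adenosine-equivalent `zeta`, so a mixed
#' tail of length `L` with `n_X` residues of type `X` behaves like a pure
#' poly(A) of `(number of A) + sum(n_X * zeta_X)` nucleotides with respect
#' to total shortening time. Interactions between closely spaced non-A
#' residues are not modeled (a warning is issued when a supplied tail
#' sequence places two non-As within 2 nt of each other).
#'
#' @param tail_length Designed tail length `L` in nt, or a tail sequence
#'   string (5'->3') from which length and composition are derived.
#' @param composition Named counts of non-A residues, e.g. `c(G = 10)`
#'   (ignored when `tail_length` is a sequence).
#' @param zeta Named adenosine-equivalents per residue type, e.g.
#'   `c(G = 6, U = 8, C = 11)`.
#' @return A tibble with `tail_length`, `n_non_a`, `effective_length` (nt)
#'   and `fold_change` relative to `L`.
#' @examples
#' effective_tail_length(100, c(G = 10), zeta = c(G = 6)) # 150 nt
#' @export
effective_tail_length <- function(tail_length, composition = NULL,
                                  zeta = c(G = 6, U = 8, C = 11)) {
  if (is.character(tail_length)) {
    seq <- toupper(gsub("T", "U", tail_length))
    chars <- strsplit(seq, "")[[1]]
    if (!all(chars %in% c("A", "G", "U", "C"))) abort("Tail sequence must be over {A,G,U,C}.")
    pos_non_a <- which(chars != "A")
    if (length(pos_non_a) > 1 && min(diff(pos_non_a)) <= 2) {
      warn("Non-A residues within 2 nt of each other; interaction effects are not modeled.")
    }
    composition <- table(chars[pos_non_a])
    composition <- setNames(as.numeric(composition), names(composition))
    tail_length <- length(chars)
  }
  composition <- composition %||% numeric(0)
  if (any(composition < 0)) abort("Residue counts must be nonnegative.")
  if (sum(composition) > tail_length) abort("Non-A counts exceed the tail length.")
  if (length(composition)) {
    missing <- setdiff(names(composition), names(zeta))
    if (length(missing)) {
      abort(sprintf("No zeta value for residue type(s) %s.", paste(missing, collapse = ", ")))
    }
    zz <- zeta[names(composition)]
    if (any(zz < 1)) warn("zeta < 1 implies faster-than-adenosine removal; check inputs.")
  } else {
    zz <- numeric(0)
  }
  n_a <- tail_length - sum(composition)
  eff <- n_a + sum(composition * zz)
  tibble(
    tail_length = tail_length,
    n_non_a = sum(composition),
    effective_length = eff,
    fold_change = eff / tail_length
  )
}
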