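#' Preset stalling factor tables
#'
#' Multiplicative rate reductions applied at offsets (-2, -1, 0) around a
#' non-A residue, per residue type, for three enzyme-complex variants:
#' the full wild-type complex, a complex with only the CAF1 nuclease active
#' (`"caf1_only"`) and one with only CCR4 active (`"ccr4_only"`). The
#' numbers are synthetic stand-ins chosen to reproduce the qualitative
#' signatures of the real complexes — wild-type guanosine stalls mainly at
#' -1; the CAF1-active complex stalls at -2/-1 but little at 0; the
#' CCR4-active complex barely stalls at -2 for guanosine, pauses at 0, and
#' is inhibited far more strongly by pyrimidines than by guanosine — with
#' flat-baseline effect sizes in the ranges reported for such assays.
#'
#' @param variant `"wild_type"`, `"caf1_only"` or `"ccr4_only"`.
#' @return A tibble with `residue`, `f_m2`, `f_m1`, `f_0` (factors in
#'   (0, 1]).
#' @export
stall_factor_table <- function(variant = c("wild_type", "caf1_only", "ccr4_only")) {
  variant <- match.arg(variant)
  tab <- switch(variant,
    wild_type = tibble(
      residue = c("G", "U", "C"),
      f_m2 = c(0.60, 0.32, 0.24),
      f_m1 = c(0.22, 0.30, 0.22),
      f_0  = c(0.70, 0.32, 0.24)
    ),
    caf1_only = tibble(
      residue = c("G", "U", "C"),
      f_m2 = c(0.28, 0.25, 0.20),
      f_m1 = c(0.30, 0.27, 0.22),
      f_0  = c(0.75, 0.55, 0.50)
    ),
    ccr4_only = tibble(
      residue = c("G", "U", "C"),
      f_m2 = c(0.85, 0.33, 0.30),
      f_m1 = c(0.45, 0.10, 0.09),
      f_0  = c(0.30, 0.14, 0.13)
    )
  )
  tab$variant <- variant
  tab
}

variant_speed <- c(wild_type = 1.0, caf1_only = 0.6, ccr4_only = 0.25)

#' Define a synthetic deadenylation assay scenario
#'
#' A scenario bundles everything needed to generate a ground-truth assay:
#' the substrate, a baseline rate shape (rates rise over the first
#' `ramp` tail positions, then decay exponentially toward a floor —
#' the speed-up-then-gradual-deceleration shape characteristic of these
#' reactions on pure poly(A)), the per-residue stalling factors of an
#' enzyme-complex variant, the sampling times and the measurement noise.
#' The default nine time points (2, 4, 6, 8, 12, 16, 24, 32, 48 min) match
#' the assay design the model was built for. The `ccr4_only` variant is
#' deliberately slow enough that the reaction does not complete within
#' 48 min, exercising the truncated model. The scenario echoes all its
#' parameters, so a run is reproducible from the object plus a seed.
#'
#' @param substrate A [tail_substrate()] or preset name (see
#'   [substrate_preset()]).
#' @param variant Enzyme-complex variant, see [stall_factor_table()].
#' @param times Reaction times in minutes.
#' @param noise_sigma Multiplicative lognormal noise sigma (log scale);
#'   default 0.02.
#' @param baseline Named list overriding baseline shape parameters:
#'   `start`, `peak`, `ramp`, `floor`, `decay`, `speed` (rates in nt/min,
#'   `decay` per nt; `speed` scales the whole profile).
#' @param stall_factors Optional tibble replacing the preset factor table.
#' @return A list of class `deadenylation_scenario`.
#' @export
deadenylation_scenario <- function(substrate = "A20G",
                                   variant = c("wild_type", "caf1_only", "ccr4_only"),
                                   times = c(2, 4, 6, 8, 12, 16, 24, 32, 48),
                                   noise_sigma = 0.02,
                                   baseline = list(),
                                   stall_factors = NULL) {
  variant <- match.arg(variant)
  if (is.character(substrate)) substrate <- substrate_preset(substrate)
  stopifnot(inherits(substrate, "tail_substrate"))
  check_times(times)
  if (noise_sigma < 0) abort("`noise_sigma` must be nonnegative.")
  shape <- utils::modifyList(
    list(start = 0.9, peak = 1.8, ramp = 4, floor = 0.35, decay = 0.18,
         speed = unname(variant_speed[variant])),
    baseline
  )
  structure(
    list(
      substrate = substrate,
      variant = variant,
      times = as.numeric(times),
      noise_sigma = noise_sigma,
      baseline = shape,
      stall_factors = stall_factors %||% stall_factor_table(variant)
    ),
    class = "deadenylation_scenario"
  )
}

#' @export
print.deadenylation_scenario <- function(x, ...) {
  cat(sprintf(
    "<deadenylation_scenario> %s | %s | %d time points (%g..%g min) | sigma %.3g\n",
    x$substrate$name, x$variant, length(x$times), min(x$times), max(x$times),
    x$noise_sigma
  ))
  invisible(x)
}

baseline_rates <- function(shape, n_positions) {
  p <- seq_len(n_positions)
  ramp <- shape$ramp
  lam <- ifelse(
    p <= ramp,
    shape$start + (shape$peak - shape$start) * (p - 1) / max(ramp - 1, 1),
    shape$floor + (shape$peak - shape$floor) * exp(-shape$decay * (p - ramp))
  )
  lam * shape$speed
}

#' Ground-truth rate profile of a scenario
#'
#' Builds the baseline rate profile and multiplies the rates at offsets
#' (-2, -1, 0) around each non-A residue by that residue type's stalling
#' factors. Deterministic given the scenario. A non-A residue closer than
#' 2 nt to the 3' end has part of its influence zone outside the tail; the
#' affected offsets are clipped with a warning.
#'
#' @param scenario A [deadenylation_scenario()].
#' @return A [rate_profile()] tibble.
#' @export
make_rate_profile <- function(scenario) {
  stopifnot(inherits(scenario, "deadenylation_scenario"))
  sub <- scenario$substrate
  N <- tail_length(sub)
  lam <- baseline_rates(scenario$baseline, N)
  for (r in non_a_positions(sub)) {
    fac <- scenario$stall_factors[scenario$stall_factors$residue == residue(sub, r), ]
    if (nrow(fac) == 0) {
      abort(sprintf("No stall factors for residue %s.", residue(sub, r)))
    }
    targets <- r + (-2:0)
    inside <- targets >= 1 & targets <= N
    if (!all(inside)) {
      warn(sprintf(
        "Non-A at tail position %d: influence zone clipped at the 3' end.", r
      ))
    }
    f <- c(fac$f_m2, fac$f_m1, fac$f_0)[inside]
    lam[targets[inside]] <- lam[targets[inside]] * f
  }
  rate_profile(lam)
}

#' Analytic ground-truth stalling effect of a scenario
#'
#' Runs the stalling assessment on the scenario's exact rate profile
#' against its pure-A counterpart (same baseline, factors removed) — no
#' simulation or fitting involved. With factors applied only inside the
#' influence zone the baseline construction is exact and the result reduces
#' to `sum(1 / f) - 2`.
#'
#' @inheritParams make_rate_profile
#' @return A tibble as from [assess_stalling()].
#' @export
true_stalling_effect <- function(scenario) {
  sub <- scenario$substrate
  control <- scenario
  control$substrate <- tail_substrate(
    paste0(sub$name, "_pureA"), sub$body, strrep("A", tail_length(sub))
  )
  assess_stalling(
    make_rate_profile(scenario), make_rate_profile(control), sub,
    calibration = c(-3, 2)
  )
}

#' Simulate a noisy deadenylation assay
#'
#' Simulates the decay chain at the scenario's ground-truth rates and
#' times, then applies per-cell multiplicative lognormal noise
#' (`x * exp(sigma * Z)`, `Z ~ N(0,1)`): gel densitometry is positive and
#' heteroscedastic, which a lognormal captures with one parameter.
#' Reproducible given `seed`.
#'
#' @inheritParams make_rate_profile
#' @param seed Integer RNG seed.
#' @return A list: `observed` (raw noisy time course), `clean` (noise-free
#'   time course), `rates` (ground-truth [rate_profile()]), `scenario`.
#' @export
simulate_noisy_assay <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "deadenylation_scenario"))
  rates <- make_rate_profile(scenario)
  clean <- simulate_deadenylation(rates, scenario$times)
  vals <- tc_values(clean)
  if (scenario$noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- matrix(
      exp(scenario$noise_sigma * rnorm(length(vals))),
      nrow = nrow(vals)
    )
    vals <- vals * noise
  }
  list(
    observed = time_course(vals, scenario$times),
    clean = clean,
    rates = rates,
    scenario = scenario
  )
}

#' Render a time course as synthetic gel-lane profiles
#'
#' The inverse of the densitometry pipeline (up to discretization): each
#' species becomes a Gaussian band on the migration axis, with peak height
#' proportional to its abundance, centered on a uniform ladder (species 1 —
#' the intact substrate — nearest the top). A marker lane carries unit
#' bands at the intact, one-nucleotide and tailless ladder rows (the
#' A20/A1/A0-type standards used for horizontal alignment).
#'
#' @param tc A time-course tibble.
#' @param spacing Ladder spacing between band centers, in rows.
#' @param sigma_band Gaussian band width (rows). Bands closer than
#'   `2 * sigma_band` are unresolvable and trigger a warning.
#' @param offset Row of the first band center.
#' @return A named list of [lane_profile()] tibbles, one per time point
#'   (names are times in minutes) plus `"marker"`; the band-center rows are
#'   attached as attribute `"centers"`.
#' @export
render_lanes <- function(tc, spacing = 20, sigma_band = 4, offset = spacing) {
  validate_time_course(tc)
  if (spacing <= 0 || sigma_band <= 0 || offset <= 0) {
    abort("Band geometry parameters must be positive.")
  }
  if (spacing < 2 * sigma_band) {
    warn("Band spacing below 2 * sigma_band: bands will not be resolvable.")
  }
  S <- nrow(tc)
  centers <- offset + spacing * (seq_len(S) - 1L)
  axis_len <- ceiling(centers[S] + offset)
  rows <- seq_len(axis_len)
  gauss <- function(heights) {
    colSums(heights * exp(-outer(centers, rows, function(c, r) (r - c)^2) /
                            (2 * sigma_band^2)))
  }
  vals <- tc_values(tc)
  lanes <- map(seq_len(ncol(vals)), function(j) lane_profile(gauss(vals[, j])))
  names(lanes) <- format_times(tc_times(tc))
  marker_h <- numeric(S)
  marker_h[unique(c(1L, max(S - 1L, 1L), S))] <- 1
  lanes$marker <- lane_profile(gauss(marker_h))
  attr(lanes, "centers") <- centers
  lanes
}
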