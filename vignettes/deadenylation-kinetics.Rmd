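---
title: "Measuring deadenylation kinetics at single-nucleotide resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring deadenylation kinetics at single-nucleotide resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(deadkin)
```

`deadkin` turns a gel-resolved in vitro deadenylation time course into
per-nucleotide removal rates and, for mixed poly(A) tails, into the
adenosine-equivalent cost of each non-A residue. This vignette explains the
model, the estimation machinery, the stalling statistics, the synthetic-data
generator the test suite is built on, and the numerical decisions behind all
of them.

## The decay-chain model

A deadenylation assay incubates a homogeneous RNA substrate — here a short
body carrying an `N`-nucleotide tail — with a deadenylase and resolves the
reaction products on a denaturing gel at a series of time points. Each gel
species `s = 1..N+1` corresponds to one remaining tail length; `s = 1` is
the intact substrate, `s = N+1` the tailless body.

Two assumptions make the kinetics tractable at single-nucleotide
resolution:

* **First-order Markov property.** The abundance of tails of length `i`
  depends only on the state one nucleotide longer: each hydrolysis step is
  decoupled from the history of the molecule.
* **Time-independent rates.** Each position's removal rate is a constant of
  that position, not of reaction time.

Together they give a linear chain of ordinary differential equations in
tail-length coordinates,
`dx_i/dt = lambda_{i+1} x_{i+1} - lambda_i x_i`, with the tailless state
absorbing. Crucially the rates are *not* assumed equal across positions —
the whole point is to resolve their profile, which on pure poly(A) rises
over the first few nucleotides and then decelerates gradually, and on mixed
tails collapses near non-A residues.

Coordinates are a classic source of confusion. We fix them once: the tail
position `p` is counted from the 3′ terminus of the *intact* tail (`p = 1`
is the 3′-most residue, `p = N` abuts the body), and the removal event that
takes species `s` to `s + 1` hydrolyses the residue at `p = s`. All rate
profiles, stall offsets and plots use `p`.

`simulate_deadenylation()` integrates the chain with `deSolve` (`lsoda`,
stiff-capable, default `rtol = 1e-8`, `atol = 1e-10`; rates can span two
orders of magnitude across stall positions, so a non-stiff method is not
safe). Two closed forms serve as independent oracles:
`closed_form_chain()` implements the classical cascade (Bateman) solution
for pairwise-distinct rates, and `equal_rate_chain()` the truncated-Poisson
solution for a constant rate. The Bateman expansion is numerically
ill-conditioned when rates cluster — its terms alternate in sign and grow
combinatorially — so oracle comparisons use well-separated random rates
(minimum adjacent ratio 1.1 after log-uniform sampling) and leave the
near-equal regime to the Poisson form. This is a property of evaluating the
formula in double precision, not of the integrator being checked.

## From gel image to intensity matrix

The algorithmic part of densitometry starts at the 1D lane profile
(intensities summed across the lane width). Within a profile, the
separators between adjacent species are intensity minima; we rank candidate
minima by the discrete second difference of the (lightly smoothed,
moving-average width 3) profile — the points of strongest upward curvature
— and keep the strongest `n − 1`. When candidates tie at the cutoff, the
combination giving the most even segment widths wins, because gel ladders
have near-uniform single-nucleotide spacing. Manual boundary curation is
supported as an explicit `overrides` table, so a curated segmentation is
reproducible rather than an untracked edit. A band's intensity is the
*maximum* within its segment — not the integral, which is the more common
densitometry choice; peak height is what the original quantification used,
and for Gaussian-like bands of common width the two differ only by a
constant factor that normalization removes anyway.

Because a single lane only shows the species populated at that time,
`quantify_lanes()` segments a reference profile in which all bands are
visible — by default the element-wise sum of all lanes of the gel, which is
legitimate because lanes of one gel share migration rows — and applies that
segmentation to every lane.

Two normalizations are deliberately kept apart:

* `normalize_assay()` divides the whole species-by-time matrix by its
  global maximum. This is the fitting target; it removes the arbitrary
  fluorescence scale and nothing else.
* `normalize_columns()` divides each time column by its own maximum. It
  highlights the dominant species per lane and is used *only* for heatmaps
  (`plot_heatmap()`, viridis, position 1 at top); fitting to it would
  destroy the relative abundances across time that carry the kinetics.

## Rate estimation

`estimate_rates()` minimizes the element-wise difference between the
observed normalized matrix and a model prediction passed through the same
assay-wide normalization, using Levenberg–Marquardt as implemented in
`minpack.lm` (MINPACK damping). Choices that matter:

* **Positivity.** Rates are physically nonnegative. The default fits
  `lambda = exp(theta)` (smooth, unconstrained in `theta`);
  `parameterization = "box"` reproduces plain LM with a lower bound at
  zero. Both give identical answers on well-posed problems.
* **Initialization.** A scalar uniform rate that finishes the tail over the
  assay span, `N / max(times)` — scale-matched to the data without peeking
  at it.
* **Search bounds and restarts.** Exploration is capped at
  `lambda = 1e4` nt/min so the inner integration never sees pathologically
  stiff chains. The objective is multi-modal when a downstream species is
  nearly empty: a rate can be driven to its bound in a spurious local
  minimum. After convergence, any bound-pegged rate is reset to the default
  scale and the fit re-run (at most twice), keeping the better optimum.
  On noise-free synthetic assays this recovers every generating rate to
  machine precision.
* **Truncation.** Reactions that do not run to completion (slow complexes)
  carry no information about the shortest tails. `truncate_observations()`
  sums all species beyond an index `T` into species `T` — preserving column
  totals exactly — and the companion model makes `T` absorbing, estimating
  only `lambda_1..lambda_{T-1}`. `T` is interpreted in species/figure
  coordinates (tail position of the aggregated species), the only reading
  consistent with reporting "the first 11 positions" as
  `lambda_1..lambda_11`. The cut position is uncritical: fits with `T = 16`
  versus 17 agree on the first 11 rates to well under 2% on the slow
  synthetic preset.
* **Cross-validation.** `holdout_validate()` refits with lanes or single
  cells withheld and reports the withheld-cell prediction error and the
  drift of the rate vector — the standard robustness check for this kind of
  fit. At least two time points must be retained; a single lane cannot
  constrain dynamics.

### Standard errors

The default standard errors are the classical curvature-based ones:
`sigma2 * diag((J'J)^-1)` with `sigma2 = RSS/(m - k)` and `J` the
finite-difference Jacobian of the prediction at the optimum (a
finite-difference full-Hessian variant is available). This treats all
matrix cells as equally noisy. Densitometry noise, however, scales with
intensity: under multiplicative noise the informative bright cells are also
the noisiest, and the homoscedastic formula is optimistic precisely where
the data constrain the rates most — in simulation its nominal ±2 SE
intervals cover the truth for only ~75–80% of positions instead of ~95%.
`standard_errors(fit, method = "multiplicative")` therefore propagates a
relative-error model through the unweighted estimator,
`Cov = s2_rel (J'J)^-1 (J' diag(pred^2) J) (J'J)^-1`, with `s2_rel`
estimated from relative residuals of cells above a small intensity floor
(default 0.02 on the normalized scale). Its intervals are well calibrated
under multiplicative noise and it is what the recovery checks in the test
suite use; the plain formula remains the default for continuity with common
practice. Positions the reaction never reaches have a vanishing Jacobian
column and report `NA` with a warning rather than a made-up number.

## Quantifying stalling

The reciprocal rate `z_p = 1/lambda_p` is the reaction time of one removal
event. Comparing removal times around a non-A residue at tail position `r`
with a matched pure-A control gives the stalling statistics
(`no_stall_baseline()`, `stalling_effect()`):

* offsets are relative to the residue, `z(i) = z[r + i]`; the influence
  zone is `{-2, -1, 0}` (antepenultimate, penultimate, the residue itself);
* the control also slows down gradually, so "no stalling" is *not* the
  control itself but the control's slowdown rescaled into the mixed
  experiment: `b = (z(-3) - z(+2)) / (zA(-3) - zA(+2))`,
  `epsilon(i) = b (zA(-3) - zA(i))`, `z0(i) = z(-3) - epsilon(i)`;
* `zeta = sum_i z(i)/z0(i) - 2`, the residue's cost in adenosines. The
  constant −2 makes the no-stalling case come out at exactly 1 (one
  ordinary nucleotide).

The calibration offsets (−3, +2) must lie outside the influence zone; any
such pair is accepted, and with a flat control (no gradual slowdown) the
correction `epsilon` vanishes for every choice — that degenerate case is
handled explicitly rather than as a division by zero. A genuinely ambiguous
zero denominator (control equal at the two calibration offsets but not
flat in the window) is an error asking for different anchors. For the
second residue of the two-residue substrates the control is read at the
same absolute positions with the anchors shifted along (`assess_stalling()`
does this per residue automatically).

ζ uncertainty is reported as the s.e.m. across independently fit replicate
assays (`aggregate_replicates()`), matching how such experiments are
summarized; per-rate delta-method propagation through the ζ formula is
deliberately not the headline number, since replicate spread captures
gel-to-gel variability that the within-fit covariance cannot.

`effective_tail_length()` turns ζ values into design guidance: a tail of
length `L` with `n_X` residues of type `X` behaves like a pure poly(A) of
`(#A) + sum n_X zeta_X` nucleotides. The arithmetic is additive and ignores
interactions between non-A residues; the function warns when a supplied
sequence places two of them within 2 nt, where influence zones overlap and
additivity is not credible.

## The synthetic-data generator

Real gel source data for assays of this kind are generally not published in
machine-readable form, so the package carries a first-class generator
(`deadenylation_scenario()`, `make_rate_profile()`,
`simulate_noisy_assay()`, `render_lanes()`) that emulates the assay design:
a 7-mer body with 20-nt tails, pure A or with non-A residues at tail
positions 7 and 14 (`A20`, `A20G`, `A20U`, `A20C`, plus `A60`), sampled at
2, 4, 6, 8, 12, 16, 24, 32 and 48 min.

* **Baseline rate shape.** Linear rise over tail positions 1–4 followed by
  exponential decay toward a floor: `start = 0.9`, `peak = 1.8`,
  `floor = 0.35` nt/min, decay `0.18` per nt. These values make the
  noise-free wild-type pure-A reaction essentially complete within the
  48-min window (mean completion ≈ 24 min) while keeping a visible
  deceleration — the qualitative shape such assays show — without asserting
  any mechanism.
* **Complex variants.** Speed multipliers 1.0 (wild type), 0.6
  (CAF1-active) and 0.25 (CCR4-active); the last is deliberately slow
  enough that the reaction stays incomplete at 48 min, which is exactly the
  regime the truncated model exists for.
* **Stall factors.** Per residue type, multiplicative rate reductions at
  offsets (−2, −1, 0), chosen once to reproduce the qualitative
  specificities seen in such experiments (wild-type guanosine stalls mainly
  at −1; the CAF1-active complex stalls at −2/−1 and little at 0; the
  CCR4-active complex barely reacts to guanosine at −2, pauses at 0, and is
  inhibited far more by pyrimidines) with flat-baseline ζ values in the
  reported ranges (≈ 5.6 for wild-type G up to ≈ 20 for CCR4-side
  pyrimidines). Because factors act only inside the influence zone, the
  generator's ground-truth ζ reduces exactly to `sum(1/f) - 2`, which the
  analysis pipeline must and does recover.
* **Noise.** Per-cell multiplicative lognormal, `x * exp(sigma Z)`, default
  `sigma = 0.02`: densitometry is positive-valued and heteroscedastic, and
  one parameter captures that. Seeds make every assay reproducible.
* **Rendering.** `render_lanes()` is the inverse of the densitometry path
  up to discretization: one Gaussian band per species on a uniform ladder,
  peak height proportional to abundance, plus a marker lane with the
  intact/one-nucleotide/tailless standards.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real gels: band-width growth and compression along the
migration axis, spatially correlated background, lane-to-lane migration
shifts, saturation of bright bands, and any enzyme-level behaviour beyond
per-position first-order rates (no binding/dissociation sub-steps, no
processive-versus-distributive switching, no interaction between closely
spaced non-A residues).

## Problem sizes and tolerances in the test suite

The suite (runnable via `testthat`) checks, among others: oracle agreement
of the integrator with the closed forms on 100 random chains of up to 25
positions (absolute error below 1e-6 of the total mass); exact recovery of
all generating rates from noise-free assays for all twelve
substrate-variant presets (tolerance 1%, reached at machine precision);
recovery of ζ within 10% and ≥90% coverage of the true rates by ±2
multiplicative-model SEs across 20 noisy replicates at 2% noise; truncation
robustness (T = 16 vs 17, first 11 rates within 2%); and the densitometry
round trip (relative band intensities within 5% at 4-sigma band
separation). These sizes keep the full suite at a few minutes on one core
while still exercising every code path at realistic scale.

## Known limitations

* Rates are identifiable only where mass actually transits during the
  observation window; downstream positions of incomplete reactions must be
  truncated away, and their absence is reported honestly (`NA` standard
  errors) rather than imputed.
* The residual weights all matrix cells equally, as is conventional for
  this kind of fit; the multiplicative SE option corrects the *uncertainty*
  for intensity-dependent noise but the point estimate remains unweighted.
* ζ assumes the three offset contributions are independent and that the
  mixed-tail experiment's gradual slowdown is proportional to the
  control's; both are modeling commitments, not measurements.
* `effective_tail_length()` is a linear extrapolation of single-residue
  effects to designed tails; it is exactly the published worked example,
  not a kinetic simulation of long mixed tails.
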