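# deadkin

Single-nucleotide deadenylation kinetics from in vitro time-course assays.

Shortening of the mRNA poly(A) tail by the CCR4–NOT deadenylase complex is
the rate-limiting step of cytoplasmic mRNA decay, and non-adenosine residues
deposited inside the tail ("mixed tailing" by TENT4 enzymes) stall the
enzyme. `deadkin` measures how much, at the resolution of a single
nucleotide: it models a gel-resolved deadenylation time course as a
first-order Markov decay chain, estimates one removal rate per tail
position, and converts the stall caused by a single G, U or C into its
equivalent number of adenosines.

## The model

Let `x_i(t)` be the abundance of RNA whose tail retains `i` nucleotides and
`λ_i` the removal rate (nt·min⁻¹) of its 3′-terminal residue. Under
first-order Markov and time-independence assumptions the chain obeys

    dx_i/dt = λ_{i+1} x_{i+1} − λ_i x_i,

with the tailless body absorbing. Results are reported against the tail
position `p` counted from the 3′ end of the intact tail (`p = 1` is the
3′-most residue), which maps one-to-one onto gel species (`s = p`). Rates
are fit to unity-normalized band intensities by Levenberg–Marquardt
nonlinear least squares, with standard errors from the curvature at the
optimum.

Removal times are `z_p = 1/λ_p`. A non-A residue at tail position `r`
stalls the enzyme at relative offsets −2, −1 and 0; against a matched
pure-poly(A) control (which itself slows down gradually) the stalling
effect size is

    ζ = z(−2)/z_∅(−2) + z(−1)/z_∅(−1) + z(0)/z_∅(0) − 2,

where the no-stalling baseline `z_∅(i) = z(−3) − b·(z_A(−3) − z_A(i))`
rescales the control's gradual slowdown by
`b = (z(−3) − z(+2)) / (z_A(−3) − z_A(+2))`. ζ is the residue's cost in
adenosines: ζ = 1 means it behaves like one ordinary A.

## Worked example

Simulate a mixed-tail assay (7-mer body + 20-nt tail with guanosines at
tail positions 7 and 14, nine time points from 2 to 48 min, 2%
multiplicative noise), fit it together with its pure-A control, and assess
the stalling effect:

```r
library(deadkin)

sub <- substrate_preset("A20G")
sub
#> <tail_substrate> A20G: 5'-UCUACAU + AAAAAAGAAAAAAGAAAAAA-3' (tail 20 nt, non-A at 3'-positions 7, 14)

sc  <- deadenylation_scenario("A20G", "wild_type", noise_sigma = 0.02)
scA <- deadenylation_scenario("A20",  "wild_type", noise_sigma = 0.02)
fit_mixed   <- estimate_rates(simulate_noisy_assay(sc,  seed = 1)$observed)
fit_control <- estimate_rates(simulate_noisy_assay(scA, seed = 2)$observed)
fit_mixed
#> <deadenylation_fit> 20 rates from 189 cells | residual norm 0.01824 | converged (10 iter)

assess_stalling(tidy(fit_mixed), tidy(fit_control), sub)
#> # A tibble: 2 × 4
#>   anchor residue     b  zeta
#>    <int> <chr>   <dbl> <dbl>
#> 1      7 G       0.963  5.56
#> 2     14 G       0.997  5.45
```

Each guanosine in this scenario costs the enzyme about 5.5 adenosines'
worth of reaction time (the generating truth is 5.64). `tidy(fit_mixed)`
returns the per-position rate table with standard errors,
`autoplot(fit_mixed)` draws it, and `plot_heatmap()` renders the
column-normalized species-by-time heatmap in viridis. For tail design, the
adenosine-equivalents translate directly into an effective pure-poly(A)
length:

```r
effective_tail_length(100, c(G = 10), zeta = c(G = 6, U = 8, C = 11))
#> # A tibble: 1 × 4
#>   tail_length n_non_a effective_length fold_change
#>         <dbl>   <dbl>            <dbl>       <dbl>
#> 1         100      10              150         1.5
```

A 100-nt tail with ten interspersed guanosines decays like a 150-nt pure
poly(A); ten cytidines make it behave like 200 nt — a twofold increase in
total shortening time.

Gel densitometry enters through `lane_profile()` /
`find_band_boundaries()` / `quantify_bands()` (second-difference band
segmentation, per-band maxima), and `render_lanes()` generates synthetic
lane profiles to exercise that path end to end.

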