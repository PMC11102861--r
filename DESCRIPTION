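Package: deadkin
Title: Single-Nucleotide Deadenylation Kinetics from Time-Course Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures mRNA deadenylation kinetics at single-nucleotide
    resolution from in vitro time-course assays. Models poly(A) tail
    shortening as a first-order Markov decay chain of ordinary differential
    equations, estimates per-position removal rates by Levenberg-Marquardt
    nonlinear least squares with curvature-based standard errors, converts
    gel-lane densitometry profiles into species intensity matrices, and
    quantifies the stalling effect of non-adenosine residues in mixed
    poly(A) tails as equivalent numbers of adenosines. Includes a synthetic
    assay generator for end-to-end validation and viridis heatmap plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
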