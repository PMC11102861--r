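test_that("removal times invert rates and mark dead positions", {
  z <- removal_times(c(0.5, 2, 0))
  expect_equal(z$z, c(2, 0.5, NA))
  expect_equal(z$available, c(TRUE, TRUE, FALSE))
  expect_equal(removal_times(c(1, 4, 0.5) * 2)$z, removal_times(c(1, 4, 0.5))$z / 2)
  expect_error(removal_times(c(0, 0)), "All rates are zero")
})

test_that("identical experiments recover the control as baseline (b = 1)", {
  z <- removal_times(runif(20, 0.3, 2))
  base <- no_stall_baseline(z, z, anchor = 7)
  expect_equal(base$b, rep(1, 3))
  expect_equal(base$z_null, base$z_control)
  expect_equal(stalling_effect(base), 1)
})

test_that("uniform scaling of the mixed profile doubles b and the baseline", {
  set.seed(5)
  lam <- runif(20, 0.3, 2)
  z_c <- removal_times(lam)
  z_m <- z_c
  z_m$z <- 2 * z_m$z
  base <- no_stall_baseline(z_m, z_c, anchor = 7)
  expect_equal(base$b, rep(2, 3))
  expect_equal(base$z_null, 2 * base$z_control)
  expect_equal(stalling_effect(base), 1) # still no stalling relative to scale
})

test_that("a flat control gives zero slowdown correction", {
  z_c <- removal_times(rep(1, 20))
  z_m <- removal_times(c(rep(1, 4), 0.5, 0.25, 0.5, rep(1, 13)))
  base <- no_stall_baseline(z_m, z_c, anchor = 7)
  expect_equal(base$epsilon, rep(0, 3))
  expect_equal(base$z_null, rep(z_m$z[4], 3)) # z(-3) of the mixed profile
  expect_equal(stalling_effect(base), 2 + 4 + 2 - 2)
  expect_error(no_stall_baseline(z_m, z_c, anchor = 7, calibration = c(-1, 2)),
               "outside the stalled window")
  # any calibration pair outside the stalled window is allowed, and with a
  # flat control every choice gives the same answer
  alt <- no_stall_baseline(z_m, z_c, anchor = 7, calibration = c(-3, 3))
  expect_equal(stalling_effect(alt), 6)
})

test_that("the effect size obeys its defining identities", {
  df <- function(r) data.frame(z = r * c(2, 3, 4), z_null = c(2, 3, 4))
  expect_equal(stalling_effect(df(1)), 1)   # no stalling = one adenosine
  expect_equal(stalling_effect(df(2)), 4)   # uniform two-fold slowdown
  expect_equal(
    stalling_effect(data.frame(z = c(1, 3, 2), z_null = c(1, 1, 1))), 4
  )
  expect_error(stalling_effect(data.frame(z = c(1, 1, 1), z_null = c(1, 0, 1))),
               "positive")
  # scale invariance: common units cancel
  set.seed(2)
  for (i in 1:10) {
    z <- runif(3, 0.5, 5); z0 <- runif(3, 0.5, 5); c <- runif(1, 0.1, 10)
    expect_equal(
      stalling_effect(data.frame(z = c * z, z_null = c * z0)),
      stalling_effect(data.frame(z = z, z_null = z0))
    )
  }
})

test_that("assessment of generated profiles reproduces the factor algebra", {
  # with factors only inside the influence zone, zeta = sum(1/f) - 2 exactly
  sc <- deadenylation_scenario("A20G", "wild_type", noise_sigma = 0)
  f <- stall_factor_table("wild_type")
  f <- f[f$residue == "G", ]
  expected <- 1 / f$f_m2 + 1 / f$f_m1 + 1 / f$f_0 - 2
  got <- true_stalling_effect(sc)
  expect_equal(got$zeta, rep(expected, 2))
  expect_equal(got$b, rep(1, 2))
  expect_equal(got$anchor, c(7L, 14L))
  # flat baseline, custom factors: 1/0.5 + 1/0.2 + 1/0.5 - 2 = 7
  sc2 <- deadenylation_scenario(
    "A20G", "wild_type", noise_sigma = 0,
    baseline = list(start = 1, peak = 1, floor = 1, decay = 0),
    stall_factors = tibble::tibble(residue = "G", f_m2 = 0.5, f_m1 = 0.2, f_0 = 0.5)
  )
  expect_equal(true_stalling_effect(sc2)$zeta, c(7, 7))
})

test_that("replicate aggregation reports mean and s.e.m. per group", {
  tbl <- tibble::tibble(
    residue = c("G", "G", "U", "C", "C"),
    zeta = c(4, 6, 5, 7, 7)
  )
  agg <- aggregate_replicates(tbl, residue)
  expect_equal(agg$mean_zeta[agg$residue == "G"], 5)
  expect_equal(agg$sem[agg$residue == "G"], 1) # sd = sqrt(2), /sqrt(2)
  expect_true(is.na(agg$sem[agg$residue == "U"]))
  expect_equal(agg$sem[agg$residue == "C"], 0)
  expect_error(aggregate_replicates(tbl[0, ], residue), "non-empty")
})

test_that("effective tail length follows the adenosine-equivalent arithmetic", {
  expect_equal(effective_tail_length(100, c(G = 10))$effective_length, 150)
  expect_equal(effective_tail_length(100, c(U = 10))$effective_length, 170)
  res <- effective_tail_length(100, c(C = 10))
  expect_equal(res$effective_length, 200)
  expect_equal(res$fold_change, 2)
  pure <- effective_tail_length(20)
  expect_equal(pure$effective_length, 20)
  expect_equal(pure$fold_change, 1)
  # additivity over residue types
  mix <- effective_tail_length(100, c(G = 5, C = 5))
  expect_equal(mix$effective_length, 90 + 5 * 6 + 5 * 11)
  expect_error(effective_tail_length(10, c(G = 11)), "exceed")
  expect_error(effective_tail_length(10, c(G = -1)), "nonnegative")
  expect_warning(effective_tail_length(10, c(G = 1), zeta = c(G = 0.5)), "zeta < 1")
})

test_that("tail sequences are parsed and close spacing is flagged", {
  seq <- paste0(strrep("A", 10), "G", strrep("A", 9)) # one G, well separated
  expect_equal(effective_tail_length(seq)$effective_length, 19 + 6)
  close <- paste0(strrep("A", 8), "GG", strrep("A", 10))
  expect_warning(res <- effective_tail_length(close), "within 2 nt")
  expect_equal(res$effective_length, 18 + 12)
})
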