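test_that("rate profiles apply stall factors at the right positions", {
  unity <- tibble::tibble(residue = "G", f_m2 = 1, f_m1 = 1, f_0 = 1)
  scG <- deadenylation_scenario("A20G", stall_factors = unity, noise_sigma = 0)
  scA <- deadenylation_scenario("A20", noise_sigma = 0)
  expect_equal(make_rate_profile(scG)$lambda, make_rate_profile(scA)$lambda)

  only_m1 <- tibble::tibble(residue = "G", f_m2 = 1, f_m1 = 0.2, f_0 = 1)
  sc <- deadenylation_scenario("A20G", stall_factors = only_m1, noise_sigma = 0)
  lam <- make_rate_profile(sc)$lambda
  base <- make_rate_profile(scA)$lambda
  expect_equal(lam[c(6, 13)], 0.2 * base[c(6, 13)])
  expect_equal(lam[-c(6, 13)], base[-c(6, 13)])
})

test_that("a non-A too close to the 3' end clips its influence zone", {
  sub <- tail_substrate("G1", "UCUACAU", paste0(strrep("A", 9), "G")) # G at p = 1
  sc <- deadenylation_scenario(sub, noise_sigma = 0)
  expect_warning(prof <- make_rate_profile(sc), "clipped")
  expect_equal(nrow(prof), 10)
})

test_that("the baseline shape rises over the ramp then decelerates", {
  lam <- make_rate_profile(deadenylation_scenario("A20", noise_sigma = 0))$lambda
  expect_true(all(diff(lam[1:4]) > 0))
  expect_true(all(diff(lam[4:20]) < 0))
  expect_true(all(lam > 0))
})

test_that("noisy assays are seeded, reproducible, and unbiased on the log scale", {
  sc0 <- deadenylation_scenario("A20G", noise_sigma = 0)
  sim0 <- simulate_noisy_assay(sc0, seed = 1)
  expect_equal(sim0$observed, sim0$clean)

  sc <- deadenylation_scenario("A20G", noise_sigma = 0.05)
  a <- simulate_noisy_assay(sc, seed = 99)
  b <- simulate_noisy_assay(sc, seed = 99)
  expect_identical(a$observed, b$observed)
  c <- simulate_noisy_assay(sc, seed = 100)
  expect_false(identical(a$observed, c$observed))
  expect_error(
    deadenylation_scenario("A20G", noise_sigma = -0.1), "nonnegative"
  )

  # per-cell mean log-ratio across seeds is centred at zero
  ratios <- sapply(1:20, function(s) {
    sim <- simulate_noisy_assay(sc, seed = s)
    o <- tc_values(sim$observed); cl <- tc_values(sim$clean)
    keep <- cl > 0
    r <- rep(NA_real_, length(cl)); r[keep] <- log(o[keep] / cl[keep]); r
  })
  cell_means <- rowMeans(ratios)
  cell_means <- cell_means[!is.na(cell_means)]
  bound <- 3 * 0.05 / sqrt(20)
  expect_gt(mean(abs(cell_means) <= bound), 0.99)  # per-cell 3-sigma check
  expect_true(all(abs(cell_means) <= 4 * 0.05 / sqrt(20)))
  expect_lt(abs(mean(cell_means)), bound / sqrt(length(cell_means)) * 3)
})

test_that("lanes render one Gaussian band per populated species", {
  tc <- time_course(matrix(c(0, 0, 2, 0, 0), ncol = 1), times = 5)
  lanes <- render_lanes(tc, spacing = 20, sigma_band = 4)
  prof <- lanes[["5"]]
  centers <- attr(lanes, "centers")
  expect_equal(prof$row[which.max(prof$intensity)], centers[3])
  expect_equal(max(prof$intensity), 2, tolerance = 1e-6)

  flat <- render_lanes(time_course(matrix(0, 3, 1), times = 1))
  expect_equal(max(flat[["1"]]$intensity), 0)
  expect_warning(render_lanes(tc, spacing = 5, sigma_band = 4), "resolvable")
  expect_error(render_lanes(tc, spacing = -1), "positive")
  expect_true("marker" %in% names(lanes))
})

test_that("preset scenarios show the characteristic accumulation signatures", {
  # single-G tails pile up at the penultimate species (6 and 13)
  scG <- deadenylation_scenario("A20G", "wild_type", noise_sigma = 0)
  cnG <- tc_values(normalize_columns(simulate_noisy_assay(scG)$clean))
  expect_true(all(c(6, 13) %in% apply(cnG, 2, which.max)))
  # pyrimidines spread the stall over species 5-7 and 12-14
  scU <- deadenylation_scenario("A20U", "wild_type", noise_sigma = 0)
  cnU <- tc_values(normalize_columns(simulate_noisy_assay(scU)$clean))
  peaks <- apply(cnU, 2, which.max)
  expect_true(all(c(5, 6, 7) %in% peaks) || all(cnU[5:7, 4] > 0.4))
  expect_true(any(peaks %in% 12:14))
})

test_that("factor presets respect the qualitative subunit specificities", {
  for (v in c("wild_type", "caf1_only", "ccr4_only")) {
    tab <- stall_factor_table(v)
    expect_true(all(tab[c("f_m2", "f_m1", "f_0")] > 0 &
                      tab[c("f_m2", "f_m1", "f_0")] <= 1))
    zeta <- with(tab, 1 / f_m2 + 1 / f_m1 + 1 / f_0 - 2)
    # pyrimidines stall harder than guanosine in every complex variant
    expect_true(all(zeta[tab$residue %in% c("U", "C")] > zeta[tab$residue == "G"]))
  }
  ccr4 <- stall_factor_table("ccr4_only")
  expect_gte(ccr4$f_m2[ccr4$residue == "G"], 0.8) # weak -2 stalling for G
})

test_that("the slow preset leaves the reaction visibly incomplete at 48 min", {
  sc <- deadenylation_scenario("A20U", "ccr4_only", noise_sigma = 0)
  v <- tc_values(simulate_noisy_assay(sc)$clean)
  expect_lt(sum(v[17:21, ncol(v)]), 0.02) # almost nothing beyond species 16
  expect_gt(sum(v[10:16, ncol(v)]), 0.1)  # but mass is en route
})
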