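make_clean_obs <- function(substrate = "A20", variant = "wild_type") {
  sc <- deadenylation_scenario(substrate, variant, noise_sigma = 0)
  sim <- simulate_noisy_assay(sc)
  list(obs = normalize_assay(sim$observed), truth = sim$rates$lambda, sc = sc)
}

test_that("residuals vanish at the generating rates and localise perturbations", {
  d <- make_clean_obs()
  res <- fit_residuals(d$obs, d$truth)
  expect_lt(max(abs(res)), 1e-8)
  bumped <- tc_values(d$obs)
  bumped[5, 3] <- bumped[5, 3] + 0.1
  res2 <- fit_residuals(time_course(bumped, tc_times(d$obs)), d$truth)
  expect_equal(sum(abs(res2) > 1e-8), 1L)
  expect_equal(max(res2), 0.1, tolerance = 1e-7)
  expect_error(fit_residuals(d$obs, d$truth[-1]), "Need 20 rates")
})

test_that("a single-step chain inverts the exponential exactly", {
  times <- c(2, 4, 6, 8, 12, 16, 24, 32, 48)
  intact <- exp(-0.3 * times)
  obs <- time_course(rbind(intact, 1 - intact), times)
  fit <- estimate_rates(obs)
  expect_equal(fit$rates$lambda, 0.3, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_error(estimate_rates(time_course(matrix(0, 2, 9), times)), "all zero")
})

test_that("noise-free assays return the generating rates in both parameterizations", {
  d <- make_clean_obs("A20G")
  for (par in c("log", "box")) {
    fit <- estimate_rates(d$obs, parameterization = par)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$rates$lambda - d$truth) / d$truth), 0.01)
    expect_lt(max(fit$rates$se, na.rm = TRUE), 1e-4) # zero-residual limit
  }
})

test_that("estimates are invariant to the raw intensity scale", {
  d <- make_clean_obs("A20U")
  raw <- time_course(tc_values(d$obs) * 5400, tc_times(d$obs))
  f1 <- estimate_rates(d$obs)
  f2 <- estimate_rates(raw)
  expect_equal(f1$rates$lambda, f2$rates$lambda, tolerance = 1e-8)
})

test_that("the reported prediction reproduces the fit residual norm", {
  d <- make_clean_obs("A20G")
  sc_noisy <- deadenylation_scenario("A20G", noise_sigma = 0.02)
  obs <- normalize_assay(simulate_noisy_assay(sc_noisy, seed = 3)$observed)
  fit <- estimate_rates(obs)
  again <- sqrt(sum(fit_residuals(obs, fit$rates$lambda)^2))
  expect_equal(again, fit$residual_norm, tolerance = 1e-10)
  expect_equal(dim(tc_values(fit$predicted)), dim(tc_values(obs)))
  g <- glance(fit)
  expect_equal(g$rss, fit$residual_norm^2)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("standard errors track the replicate spread of the estimates", {
  set.seed(11)
  lam <- c(1, 0.8, 0.6, 0.9, 1.2)
  times <- c(2, 4, 6, 8, 12, 16, 24, 32, 48)
  clean <- simulate_deadenylation(lam, times)
  hats <- NULL
  ses <- NULL
  for (i in 1:15) {
    noisy <- tc_values(clean) * exp(0.02 * rnorm(length(tc_values(clean))))
    fit <- estimate_rates(time_course(noisy, times))
    hats <- rbind(hats, fit$rates$lambda)
    ses <- rbind(ses, fit$rates$se)
  }
  emp <- apply(hats, 2, sd)
  med_se <- apply(ses, 2, stats::median)
  expect_true(all(med_se / emp > 1 / 3 & med_se / emp < 3))
})

test_that("positions the reaction never reaches have no standard error", {
  # stop sampling at 6 min: the wild-type reaction has not yet gone far,
  # so late positions carry no information at all
  sc <- deadenylation_scenario("A20", noise_sigma = 0, times = c(2, 4, 6))
  obs <- simulate_noisy_assay(sc)$observed
  expect_warning(
    fit <- estimate_rates(obs),
    "standard errors unavailable"
  )
  expect_true(any(is.na(fit$rates$se)))
  expect_true(all(!is.na(fit$rates$se[1:8])))
})

test_that("truncation aggregates tail mass and preserves column totals", {
  d <- make_clean_obs("A20U", "ccr4_only")
  raw <- simulate_noisy_assay(d$sc)$observed
  tr <- truncate_observations(raw, 16)
  expect_equal(nrow(tr), 16)
  expect_equal(colSums(tc_values(tr)), colSums(tc_values(raw)))
  # no mass beyond T: truncation is the identity on the kept rows
  early <- time_course(tc_values(raw)[1:16, , drop = FALSE] , tc_times(raw))
  none_beyond <- truncate_observations(early, 16)
  expect_equal(tc_values(none_beyond)[1:15, ], tc_values(early)[1:15, ])
  expect_error(truncate_observations(raw, 1), "species index")
  expect_error(truncate_observations(raw, 22), "species index")
})

test_that("the choice of truncation point barely moves the early rates", {
  d <- make_clean_obs("A20U", "ccr4_only") # reaction incomplete by 48 min
  f16 <- fit_quietly(d$obs, truncate_at = 16)
  f18 <- fit_quietly(d$obs, truncate_at = 18)
  rel <- abs(f16$rates$lambda[1:11] - f18$rates$lambda[1:11]) /
    f18$rates$lambda[1:11]
  expect_lt(max(rel), 0.02)
})

test_that("holdout validation predicts withheld lanes and bounds rate drift", {
  d <- make_clean_obs("A20G")
  rep <- holdout_validate(d$obs, holdout_times = 8)
  expect_lt(rep$max_error, 1e-3)
  expect_lt(rep$rate_distance, 0.01)
  none <- holdout_validate(d$obs)
  expect_equal(none$rate_distance, 0)
  expect_equal(nrow(none$cells), 0)
  expect_error(
    holdout_validate(d$obs, holdout_times = c(2, 4, 6, 8, 12, 16, 24, 32)),
    "at least two time points"
  )
})

test_that("fully withheld positions are excluded from the comparison", {
  d <- make_clean_obs("A20G")
  cells <- expand.grid(position = 21, time = tc_times(d$obs))
  expect_warning(
    rep <- holdout_validate(d$obs, holdout_cells = cells),
    "fully withheld"
  )
  expect_equal(rep$excluded_positions, 21L)
})

test_that("non-overlapping error-bar pairs are reported", {
  rates <- tibble::tibble(
    position = 1:3, lambda = c(1, 2, 1.05), se = c(0.1, 0.1, 0.1)
  )
  cmp <- nonoverlapping_intervals(rates)
  expect_true(cmp$distinct[cmp$position_a == 1 & cmp$position_b == 2])
  expect_false(cmp$distinct[cmp$position_a == 1 & cmp$position_b == 3])
})
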