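#' Per-position removal-rate profiles
#'
#' A rate profile holds one removal rate per tail position `p = 1..N`
#' (3'-anchored; see [tail_substrate()]), in nt per minute: `lambda[p]` is
#' the rate of the hydrolysis event taking species `s = p` to `s = p + 1`.
#' The tailless body is absorbing, so no rate is defined beyond `p = N`.
#'
#' @param lambda Nonnegative removal rates, one per tail position.
#' @param se Optional standard errors (same length and units).
#' @return A tibble with columns `position`, `lambda` and optionally `se`.
#' @export
rate_profile <- function(lambda, se = NULL) {
  lambda <- as.numeric(lambda)
  if (length(lambda) == 0 || any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("Rates must be finite and nonnegative.")
  }
  out <- tibble(position = seq_along(lambda), lambda = lambda)
  if (!is.null(se)) {
    se <- as.numeric(se)
    if (length(se) != length(lambda)) abort("`se` must match `lambda` in length.")
    out$se <- se
  }
  out
}

as_rates <- function(rates) {
  if (is.data.frame(rates)) {
    if (!all(c("position", "lambda") %in% names(rates))) {
      abort("A rate profile needs `position` and `lambda` columns.")
    }
    rates <- rates$lambda[order(rates$position)]
  }
  rates <- as.numeric(rates)
  if (length(rates) == 0 || any(!is.finite(rates)) || any(rates < 0)) {
    abort("Rates must be finite and nonnegative.")
  }
  rates
}

#' Simulate deadenylation as a first-order Markov decay chain
#'
#' Integrates the linear chain of ordinary differential equations
#' `dx_i/dt = lambda_{i+1} x_{i+1} - lambda_i x_i` (written in tail-length
#' coordinates; equivalently, species `s` gains from `s - 1` at rate
#' `lambda_{s-1}` and loses to `s + 1` at rate `lambda_s`). Total abundance
#' is conserved; the tailless species is absorbing.
#'
#' Integration uses [deSolve::ode()] with a stiff-capable method, since
#' stall positions can make rates span orders of magnitude.
#'
#' @param rates A [rate_profile()] tibble or numeric vector of length `N`.
#' @param times Output times in minutes, strictly increasing, nonnegative.
#' @param x0 Initial species abundances, length `N + 1`; default puts unit
#'   mass on the intact substrate.
#' @param rtol,atol Integrator tolerances.
#' @return A [time_course()] tibble over species `1..N+1` at `times`.
#' @examples
#' tc <- simulate_deadenylation(rep(1, 20), times = c(2, 4, 8, 16))
#' mass_balance(tc)
#' @export
simulate_deadenylation <- function(rates, times, x0 = NULL,
                                   rtol = 1e-8, atol = 1e-10) {
  lambda <- as_rates(rates)
  n_species <- length(lambda) + 1L
  check_times(times)
  if (any(times < 0)) abort("`times` must be nonnegative.")
  x0 <- x0 %||% c(1, rep(0, n_species - 1L))
  x0 <- as.numeric(x0)
  if (length(x0) != n_species) {
    abort(sprintf("`x0` must have length %d (species 1..N+1).", n_species))
  }
  if (any(!is.finite(x0)) || any(x0 < 0)) {
    abort("`x0` must be finite and nonnegative.")
  }

  # outflow rate per species: lambda_s for s <= N, 0 for the absorbing body
  out_rate <- c(lambda, 0)
  deriv <- function(t, x, parms) {
    flux <- out_rate * x
    list(c(-flux[1], flux[-n_species] - flux[-1]))
  }
  t_grid <- if (times[1] > 0) c(0, times) else times
  sol <- suppressWarnings(deSolve::ode(
    y = x0, times = t_grid, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  ))
  if (nrow(sol) < length(t_grid)) {
    abort("ODE integration failed before reaching the final time point.")
  }
  vals <- t(unname(sol[, -1, drop = FALSE]))
  if (times[1] > 0) vals <- vals[, -1, drop = FALSE]
  # integrator can leave tiny negative values near zero; clip within atol
  vals[vals < 0 & vals > -atol * 100] <- 0
  time_course(vals, times)
}

#' Closed-form solution of the decay chain (Bateman equations)
#'
#' Analytic solution for a unidirectional first-order chain with pairwise
#' distinct rates and all initial mass on the intact species. Serves as an
#' independent oracle for [simulate_deadenylation()]. The classical formula
#' is numerically ill-conditioned when rates cluster; use the equal-rate
#' form [equal_rate_chain()] or the numeric path in that regime.
#'
#' @inheritParams simulate_deadenylation
#' @param x0_total Total initial abundance placed on species 1.
#' @return A [time_course()] tibble over species `1..N+1`.
#' @export
closed_form_chain <- function(rates, times, x0_total = 1) {
  lambda <- as_rates(rates)
  if (any(lambda <= 0)) abort("Closed form requires strictly positive rates.")
  if (anyDuplicated(lambda)) {
    abort("Closed form requires pairwise-distinct rates; perturb or use the numeric path.")
  }
  check_times(times)
  n <- length(lambda)
  vals <- matrix(0, nrow = n + 1L, ncol = length(times))
  for (s in seq_len(n)) {
    lam <- lambda[seq_len(s)]
    # x_s(t) = prod(lambda_1..s-1) * sum_m exp(-lambda_m t) / prod_{k!=m}(lambda_k - lambda_m)
    coefs <- vapply(seq_len(s), function(m) {
      prod(head(lam, s - 1)) / prod(lam[-m] - lam[m])
    }, numeric(1))
    if (s == 1) coefs <- 1
    vals[s, ] <- as.vector(coefs %*% exp(-outer(lam, times)))
  }
  vals[n + 1L, ] <- 1 - colSums(vals[seq_len(n), , drop = FALSE])
  vals[vals < 0 & vals > -1e-12] <- 0
  time_course(vals * x0_total, times)
}

#' Closed-form chain with equal rates (truncated Poisson)
#'
#' With a common rate `c` the number of removals by time `t` is Poisson with
#' mean `c * t`, truncated by absorption at the tailless state: species
#' `s = 1 + k` (for `k < N`) has abundance `exp(-ct) (ct)^k / k!` and the
#' body accumulates the remaining tail probability.
#'
#' @param rate Common removal rate (nt/min).
#' @param n_positions Tail length `N`.
#' @inheritParams closed_form_chain
#' @return A [time_course()] tibble over species `1..N+1`.
#' @export
equal_rate_chain <- function(rate, n_positions, times, x0_total = 1) {
  stopifnot(rate > 0, n_positions >= 1)
  check_times(times)
  vals <- vapply(times, function(t) {
    k <- 0:(n_positions - 1L)
    c(dpois(k, rate * t), ppois(n_positions - 1L, rate * t, lower.tail = FALSE))
  }, numeric(n_positions + 1L))
  time_course(vals * x0_total, times)
}
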