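#' Residuals between an observed assay and the chain model
#'
#' The fitting cost is the element-wise difference between the observed
#' unity-normalized intensities and the model prediction, where the
#' prediction is a chain simulation passed through the *same* assay-wide
#' normalization ([normalize_assay()]). Normalizing both sides removes the
#' unknown fluorescence scale without adding a free parameter.
#'
#' @param observed Normalized time-course tibble (max entry 1).
#' @param rates A [rate_profile()] tibble or numeric vector of length
#'   `nrow(observed) - 1`.
#' @param x0 Initial condition passed to [simulate_deadenylation()].
#' @param mask Optional logical species-by-time matrix; `FALSE` cells are
#'   excluded (residual 0).
#' @param rtol,atol Integrator tolerances.
#' @return Numeric vector `observed - predicted`, flattened species-major.
#' @export
fit_residuals <- function(observed, rates, x0 = NULL, mask = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  validate_time_course(observed)
  lambda <- as_rates(rates)
  if (length(lambda) != nrow(observed) - 1L) {
    abort(sprintf(
      "Need %d rates for %d species; got %d.",
      nrow(observed) - 1L, nrow(observed), length(lambda)
    ))
  }
  obs <- tc_values(observed)
  pred <- predicted_norm(lambda, tc_times(observed), x0, rtol, atol)
  res <- obs - pred
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(obs))) abort("`mask` must match the matrix shape.")
    res[!mask] <- 0
  }
  as.vector(res)
}

predicted_norm <- function(lambda, times, x0, rtol, atol) {
  tc <- simulate_deadenylation(lambda, times, x0 = x0, rtol = rtol, atol = atol)
  m <- max(tc_values(tc))
  tc_values(tc) / m
}

#' Estimate per-position deadenylation rates
#'
#' Fits the decay-chain model to a normalized species-by-time intensity
#' matrix by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nls.lm()], the MINPACK damping policy). Rates are kept
#' nonnegative either by fitting in log-rate space (`lambda = exp(theta)`,
#' the default) or by box constraints (`parameterization = "box"`, plain LM
#' with a lower bound at zero). Standard errors come from the curvature at
#' the optimum (see [standard_errors()]). The returned object carries the
#' in-silico re-simulation from the fitted rates, so observed and predicted
#' dynamics can be compared side by side.
#'
#' @param observed Time-course tibble. If not already unity-normalized it is
#'   passed through [normalize_assay()] first (estimates are therefore
#'   invariant to the raw intensity scale).
#' @param init Starting rates: scalar or vector. Default is a uniform rate
#'   finishing the tail over the assay span, `(N / max(times))`.
#' @param truncate_at Optional species index `T`: observations beyond `T`
#'   are aggregated into species `T` ([truncate_observations()]) and only
#'   `lambda_1..lambda_{T-1}` are estimated — for reactions that do not run
#'   to completion.
#' @param parameterization `"log"` (smooth positivity) or `"box"`
#'   (constrained plain LM).
#' @param x0 Initial species abundances (default: all mass intact).
#' @param mask Optional logical matrix excluding cells from the cost.
#' @param max_iter,ftol,ptol LM control.
#' @param rtol,atol Integrator tolerances for the inner simulation.
#' @param se_method Passed to [standard_errors()].
#' @return An object of class `deadenylation_fit`; see [tidy.deadenylation_fit()].
#' @examples
#' sc <- deadenylation_scenario("A20", noise_sigma = 0)
#' obs <- normalize_assay(simulate_noisy_assay(sc, seed = 1)$observed)
#' fit <- estimate_rates(obs)
#' tidy(fit)
#' @export
estimate_rates <- function(observed, init = NULL, truncate_at = NULL,
                           parameterization = c("log", "box"),
                           x0 = NULL, mask = NULL,
                           max_iter = 400, ftol = 1e-12, ptol = 1e-12,
                           rtol = 1e-8, atol = 1e-10,
                           se_method = c("gauss_newton", "hessian")) {
  parameterization <- match.arg(parameterization)
  se_method <- match.arg(se_method)
  validate_time_course(observed)
  if (!is.null(truncate_at)) {
    observed <- truncate_observations(observed, truncate_at)
    if (!is.null(mask)) abort("`mask` cannot be combined with `truncate_at`.")
  }
  vals <- tc_values(observed)
  if (max(vals) <= 0) abort("Observed matrix is all zero; nothing to fit.")
  if (abs(max(vals) - 1) > 1e-12) observed <- normalize_assay(observed)
  times <- tc_times(observed)
  n_species <- nrow(observed)
  n_par <- n_species - 1L
  n_obs <- if (is.null(mask)) length(vals) else sum(mask)
  if (n_obs <= n_par) {
    abort("Fewer informative data cells than parameters; cannot fit.")
  }

  init <- init %||% (n_par / max(times))
  init <- rep_len(as.numeric(init), n_par)
  if (any(init <= 0)) abort("Initial rates must be positive.")

  resid_lambda <- function(lambda) {
    fit_residuals(observed, lambda, x0 = x0, mask = mask, rtol = rtol, atol = atol)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol, ptol = ptol)
  # keep LM exploration inside a physically plausible range so the inner
  # integrator never sees pathologically stiff chains
  rate_cap <- 1e4
  run_lm <- function(start) {
    fit <- if (parameterization == "log") {
      minpack.lm::nls.lm(par = log(start), fn = function(th) resid_lambda(exp(th)),
                         lower = rep(log(1e-8), n_par),
                         upper = rep(log(rate_cap), n_par), control = ctrl)
    } else {
      minpack.lm::nls.lm(par = start, fn = resid_lambda,
                         lower = rep(1e-10, n_par), upper = rep(rate_cap, n_par),
                         control = ctrl)
    }
    lambda <- if (parameterization == "log") exp(fit$par) else pmax(fit$par, 0)
    list(fit = fit, lambda = lambda, rss = sum(resid_lambda(lambda)^2))
  }
  best <- run_lm(init)
  # a rate driven to a bound can mark a spurious local minimum (the chain is
  # multi-modal when downstream species are nearly empty): restart with the
  # offending rates reset to the default scale and keep the better optimum
  for (attempt in 1:2) {
    at_bound <- best$lambda >= 0.99 * rate_cap | best$lambda <= 2e-8
    if (!any(at_bound) || best$rss < 1e-12) break
    start <- pmin(pmax(best$lambda, 1e-6), rate_cap / 10)
    start[at_bound] <- n_par / max(times)
    retry <- run_lm(start)
    if (retry$rss < best$rss * (1 - 1e-8)) best <- retry else break
  }
  fit <- best$fit
  lambda_hat <- best$lambda
  rss <- best$rss
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(sprintf(
      "LM did not converge (info %d: %s); returning partial estimates.",
      fit$info, fit$message
    ))
  }

  pred <- predicted_norm(lambda_hat, times, x0, rtol, atol)
  out <- structure(
    list(
      rates = rate_profile(lambda_hat),
      observed = observed,
      predicted = time_course(pred, times, positions = observed$position),
      residual_norm = sqrt(rss),
      rss = rss,
      iterations = fit$niter,
      converged = converged,
      info = fit$info,
      message = fit$message,
      parameterization = parameterization,
      truncate_at = truncate_at,
      x0 = x0,
      mask = mask,
      n_obs = n_obs,
      n_par = n_par,
      rtol = rtol, atol = atol
    ),
    class = "deadenylation_fit"
  )
  out$rates$se <- standard_errors(out, method = se_method)$se
  out
}

#' Standard errors of fitted rates from local curvature
#'
#' The default uses the Gauss-Newton approximation of the Hessian:
#' `Cov = sigma2 * (J'J)^-1` with `sigma2 = RSS / (m - k)` and `J` the
#' finite-difference Jacobian of the model prediction with respect to the
#' rates at the estimate. This treats every matrix cell as equally noisy;
#' densitometry errors in fact scale with intensity, which concentrates the
#' real uncertainty on the bright cells and makes the homoscedastic formula
#' optimistic for well-populated positions. `method = "multiplicative"`
#' therefore propagates a relative-error model instead:
#' `Cov = s2 * (J'J)^-1 (J' diag(pred^2) J) (J'J)^-1`, with the squared
#' relative error `s2` estimated from cells whose predicted intensity is
#' above a floor. `method = "hessian"` differentiates the full residual sum
#' of squares twice (slower; includes residual-curvature terms). Positions
#' the reaction never reaches carry no information — their Jacobian column
#' vanishes and the standard error is reported `NA` with
#' `available = FALSE`.
#'
#' @param fit A `deadenylation_fit`.
#' @param method `"gauss_newton"`, `"multiplicative"` or `"hessian"`.
#' @param floor Minimum predicted intensity (normalized scale) for a cell
#'   to enter the relative-error estimate (`"multiplicative"` only).
#' @return A tibble with `position`, `se`, `available`.
#' @export
standard_errors <- function(fit, method = c("gauss_newton", "multiplicative", "hessian"),
                            floor = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "deadenylation_fit"))
  lambda <- fit$rates$lambda
  k <- length(lambda)
  resid_fun <- function(l) {
    fit_residuals(fit$observed, l, x0 = fit$x0, mask = fit$mask,
                  rtol = fit$rtol, atol = fit$atol)
  }
  sigma2 <- fit$rss / max(fit$n_obs - k, 1)
  h <- pmax(1e-6, 1e-4 * lambda)

  m_cells <- nrow(fit$observed) * length(tc_times(fit$observed))

  if (method %in% c("gauss_newton", "multiplicative")) {
    J <- vapply(seq_len(k), function(p) {
      up <- dn <- lambda
      up[p] <- lambda[p] + h[p]
      dn[p] <- max(lambda[p] - h[p], 0)
      -(resid_fun(up) - resid_fun(dn)) / (up[p] - dn[p])
    }, numeric(m_cells))
    colnorm <- colSums(J^2)
    available <- colnorm > 1e-10 * max(colnorm, 1)
    se <- rep(NA_real_, k)
    if (any(available)) {
      Ja <- J[, available, drop = FALSE]
      JtJ <- crossprod(Ja)
      cov_try <- tryCatch({
        A_inv <- chol2inv(chol(JtJ))
        if (method == "gauss_newton") {
          sigma2 * A_inv
        } else {
          pred <- as.vector(tc_values(fit$predicted))
          r <- resid_fun(lambda)
          used <- pred > floor
          if (!is.null(fit$mask)) used <- used & as.vector(fit$mask)
          if (sum(used) <= sum(available)) {
            abort("Too few cells above the intensity floor for relative-error estimation.")
          }
          s2_rel <- sum((r[used] / pred[used])^2) / (sum(used) - sum(available))
          meat <- crossprod(Ja * pred, Ja * pred)
          s2_rel * A_inv %*% meat %*% A_inv
        }
      }, error = function(e) NULL)
      if (is.null(cov_try)) {
        warn("Curvature matrix is singular; standard errors unavailable.")
        available[] <- FALSE
      } else {
        se[available] <- sqrt(pmax(diag(cov_try), 0))
      }
    }
    if (!all(available)) {
      warn(sprintf(
        "No signal at position(s) %s; standard errors unavailable there.",
        paste(which(!available), collapse = ", ")
      ))
    }
  } else {
    rss_fun <- function(l) sum(resid_fun(pmax(l, 0))^2)
    H <- matrix(0, k, k)
    for (i in seq_len(k)) {
      for (j in i:k) {
        ei <- ej <- numeric(k)
        ei[i] <- h[i]; ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (rss_fun(lambda + ei + ej) - rss_fun(lambda + ei - ej) -
             rss_fun(lambda - ei + ej) + rss_fun(lambda - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
    cov_try <- tryCatch(sigma2 * solve(H / 2), error = function(e) NULL)
    available <- rep(!is.null(cov_try), k)
    se <- rep(NA_real_, k)
    if (!is.null(cov_try)) se <- sqrt(pmax(diag(cov_try), 0))
    else warn("Full Hessian is singular; standard errors unavailable.")
  }
  tibble(position = seq_len(k), se = se, available = available)
}

#' Flag pairs of positions with non-overlapping error bars
#'
#' Error bars (`lambda +/- se`) that do not overlap indicate a substantial
#' change in deadenylation kinetics between two positions.
#'
#' @param rates A rate tibble with `position`, `lambda`, `se` (e.g.
#'   `tidy(fit)`).
#' @param multiplier Half-width of the bar in units of `se` (default 1).
#' @return A tibble of position pairs with a logical `distinct` column.
#' @export
nonoverlapping_intervals <- function(rates, multiplier = 1) {
  stopifnot(all(c("position", "lambda", "se") %in% names(rates)))
  ok <- rates[!is.na(rates$se), ]
  if (nrow(ok) < 2) abort("Need at least two positions with standard errors.")
  pairs <- utils::combn(seq_len(nrow(ok)), 2)
  tibble(
    position_a = ok$position[pairs[1, ]],
    position_b = ok$position[pairs[2, ]],
    distinct = (ok$lambda[pairs[1, ]] + multiplier * ok$se[pairs[1, ]] <
                  ok$lambda[pairs[2, ]] - multiplier * ok$se[pairs[2, ]]) |
               (ok$lambda[pairs[2, ]] + multiplier * ok$se[pairs[2, ]] <
                  ok$lambda[pairs[1, ]] - multiplier * ok$se[pairs[1, ]])
  )
}

#' Aggregate species beyond a truncation point
#'
#' For reactions that do not run to completion, species beyond index `T`
#' carry marginal signal; they are summed into species `T`, which the
#' companion model treats as absorbing so that only `lambda_1..lambda_{T-1}`
#' are estimated. Column totals are preserved exactly.
#'
#' @param observed A time-course tibble over species `1..S`.
#' @param at Truncation species index `T`, in `2..S`.
#' @return A time-course tibble over species `1..T`.
#' @export
truncate_observations <- function(observed, at) {
  validate_time_course(observed)
  S <- nrow(observed)
  if (length(at) != 1 || is.na(at) || at < 2 || at > S) {
    abort(sprintf("`at` must be a species index in 2..%d.", S))
  }
  vals <- tc_values(observed)
  keep <- vals[seq_len(at), , drop = FALSE]
  keep[at, ] <- colSums(vals[at:S, , drop = FALSE])
  time_course(keep, tc_times(observed), positions = observed$position[seq_len(at)])
}

#' Cross-validate a fit by withholding observations
#'
#' Refits the model with part of the data withheld (whole time points
#' and/or individual cells) and reports the prediction error on the
#' withheld cells plus the distance between the holdout and full-data rate
#' vectors — the robustness check for parameter estimation.
#'
#' @param observed Time-course tibble.
#' @param holdout_times Times (minutes) whose whole lanes are withheld.
#' @param holdout_cells Optional data frame with `position` and `time`
#'   columns naming individual cells to withhold.
#' @param ... Passed to [estimate_rates()] for both fits.
#' @return A list of class `holdout_report`: `cells` (tibble of withheld
#'   cells with observed/predicted values), `rmse`, `max_error`,
#'   `rate_distance` (max relative difference over compared positions),
#'   `excluded_positions`, and both fits.
#' @export
holdout_validate <- function(observed, holdout_times = NULL,
                             holdout_cells = NULL, ...) {
  validate_time_course(observed)
  observed <- normalize_assay(observed)
  times <- tc_times(observed)
  S <- nrow(observed)
  mask <- matrix(TRUE, S, length(times))
  if (!is.null(holdout_times)) {
    if (!all(holdout_times %in% times)) abort("`holdout_times` must be observed times.")
    mask[, times %in% holdout_times] <- FALSE
  }
  if (!is.null(holdout_cells)) {
    for (i in seq_len(nrow(holdout_cells))) {
      p <- match(holdout_cells$position[i], observed$position)
      t <- match(holdout_cells$time[i], times)
      if (is.na(p) || is.na(t)) abort("`holdout_cells` addresses a cell outside the matrix.")
      mask[p, t] <- FALSE
    }
  }
  if (sum(colSums(mask) > 0) < 2) {
    abort("Holdout must retain at least two time points.")
  }

  fit_full <- estimate_rates(observed, ...)
  fit_part <- if (all(mask)) fit_full else estimate_rates(observed, mask = mask, ...)

  obs <- tc_values(observed)
  pred <- tc_values(fit_part$predicted)
  held <- which(!mask, arr.ind = TRUE)
  cells <- tibble(
    position = observed$position[held[, 1]],
    time = times[held[, 2]],
    observed = obs[held],
    predicted = pred[held],
    error = obs[held] - pred[held]
  )
  # positions with every cell withheld cannot be compared fairly
  excluded <- observed$position[rowSums(mask) == 0]
  if (length(excluded)) {
    warn(sprintf(
      "Position(s) %s fully withheld; excluded from the rate comparison.",
      paste(excluded, collapse = ", ")
    ))
  }
  cmp <- setdiff(seq_len(S - 1L), excluded)
  lf <- fit_full$rates$lambda[cmp]
  lp <- fit_part$rates$lambda[cmp]
  structure(
    list(
      cells = cells,
      rmse = if (nrow(cells)) sqrt(mean(cells$error^2)) else 0,
      max_error = if (nrow(cells)) max(abs(cells$error)) else 0,
      rate_distance = if (length(cmp)) max(abs(lp - lf) / pmax(lf, 1e-12)) else NA_real_,
      excluded_positions = excluded,
      fit_holdout = fit_part,
      fit_full = fit_full
    ),
    class = "holdout_report"
  )
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf(
    "<holdout_report> %d withheld cell(s): rmse %.3g, max error %.3g, rate distance %.3g\n",
    nrow(x$cells), x$rmse, x$max_error, x$rate_distance
  ))
  invisible(x)
}

#' @export
print.deadenylation_fit <- function(x, ...) {
  cat(sprintf(
    "<deadenylation_fit> %d rates from %d cells | residual norm %.4g | %s (%d iter)\n",
    x$n_par, x$n_obs, x$residual_norm,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(x$rates, n = 5)
  invisible(x)
}

#' Tidiers for deadenylation fits
#'
#' `tidy()` returns the per-position rate table (`position`, `lambda`,
#' `se`); `glance()` a one-row fit summary.
#'
#' @param x A `deadenylation_fit`.
#' @param ... Unused.
#' @method tidy deadenylation_fit
#' @export
tidy.deadenylation_fit <- function(x, ...) x$rates

#' @rdname tidy.deadenylation_fit
#' @method glance deadenylation_fit
#' @export
glance.deadenylation_fit <- function(x, ...) {
  tibble(
    n_par = x$n_par, n_obs = x$n_obs,
    rss = x$rss, residual_norm = x$residual_norm,
    sigma = sqrt(x$rss / max(x$n_obs - x$n_par, 1)),
    iterations = x$iterations, converged = x$converged,
    parameterization = x$parameterization,
    truncated_at = x$truncate_at %||% NA_integer_
  )
}
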