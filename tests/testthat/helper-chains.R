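# random decay chains with well-separated rates: the Bateman closed form is
# evaluated in double precision and clustered rates make its alternating sum
# cancel catastrophically, so oracle chains keep a minimum adjacent ratio
random_chain <- function(n, min_ratio = 1.1, range = c(0.05, 20)) {
  repeat {
    lam <- sort(exp(runif(n, log(range[1]), log(range[2]))))
    if (n == 1 || min(lam[-1] / lam[-n]) >= min_ratio) break
  }
  sample(lam)
}

# fits are chatty about unavailable standard errors on purpose; tests that
# exercise incomplete reactions silence that warning only
fit_quietly <- function(...) {
  withCallingHandlers(
    estimate_rates(...),
    warning = function(w) {
      if (grepl("standard errors unavailable", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
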