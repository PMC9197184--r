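test_that("exponential MLE matches the closed form n / sum(t)", {
  ipd <- tibble::tibble(time_months = c(1, 2, 3), event = c(1, 1, 1))
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$params[["rate"]], 0.5, tolerance = 1e-5)
})

test_that("AIC identity 2k - 2 loglik holds on every family", {
  ipd <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 150, seed = 17)
  fits <- fit_all_families(ipd)
  expect_length(fits, 5)
  for (f in fits) {
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-10)
  }
  # spot value: a 2-parameter fit with loglik -100 would have AIC 204
  expect_equal(2 * 2 - 2 * (-100), 204)
})

test_that("all-censored or near-eventless input is refused", {
  ipd <- tibble::tibble(time_months = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(fit_parametric(ipd, "weibull"), class = "psmcea_invalid_input")
})

test_that("each family recovers its own parameters at n = 5000", {
  truth <- list(
    exponential = dist_spec("exponential", rate = 0.1),
    weibull     = dist_spec("weibull", shape = 1.3, scale = 11),
    lognormal   = dist_spec("lognormal", meanlog = 2.2, sdlog = 0.8),
    loglogistic = dist_spec("loglogistic", scale = 9.8, shape = 1.5),
    gompertz    = dist_spec("gompertz", shape = 0.05, rate = 0.05)
  )
  # ~20% censoring via dropout + generous cutoff
  cens <- censor_spec(admin_cutoff = 60, dropout_rate = 0.015)
  for (fam in names(truth)) {
    ipd <- simulate_ipd(truth[[fam]], cens, n = 5000, seed = 31)
    fit <- fit_parametric(ipd, fam)
    rel <- abs(fit$params - truth[[fam]]$params) /
      pmax(abs(truth[[fam]]$params), 1e-9)
    expect_true(all(rel < 0.10),
                info = sprintf("%s: %s", fam, paste(round(rel, 3), collapse = ", ")))
  }
})

test_that("log-logistic parameters recover within 5% without censoring", {
  sp <- calibrate_loglogistic(9.8, 1.5)
  ipd <- simulate_ipd(sp, censor_spec(Inf, 0), n = 5000, seed = 32)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_lt(abs(fit$params[["scale"]] - 9.8) / 9.8, 0.05)
  expect_lt(abs(fit$params[["shape"]] - 1.5) / 1.5, 0.05)
})

test_that("AIC selection prefers the generating family and breaks ties sanely", {
  sp <- calibrate_loglogistic(9.8, 1.5)
  ipd <- simulate_ipd(sp, censor_spec(), n = 5000, seed = 33)
  fits <- fit_all_families(ipd)
  expect_equal(select_best(fits)$family, "loglogistic")
  # identity on a single fit
  expect_identical(select_best(fits["weibull"]), fits$weibull)
  # direct AIC comparison
  expect_lt(fits$loglogistic$aic, fits$exponential$aic)
  expect_error(select_best(list()), class = "psmcea_empty_input")
})

test_that("survival and hazard evaluators agree with quadrature", {
  fits <- list(dist_spec("weibull", shape = 1.4, scale = 10),
               dist_spec("gompertz", shape = 0.08, rate = 0.04),
               dist_spec("lognormal", meanlog = 2.2, sdlog = 0.9))
  for (sp in fits) {
    expect_equal(dist_survival(sp, 0), 1)
    for (tt in c(3, 8, 15)) {
      H <- integrate(function(u) dist_hazard(sp, u), 0, tt, rel.tol = 1e-9)$value
      expect_equal(-log(dist_survival(sp, tt)), H, tolerance = 1e-3)
    }
  }
  expect_error(dist_survival(fits[[1]], -1), class = "psmcea_invalid_parameter")
})

test_that("hazard-ratio transformation is a proper proportional-hazards power", {
  ref <- calibrate_loglogistic(9.8, 1.5)
  ident <- apply_hr(ref, 1)
  tt <- seq(0, 40, by = 0.5)
  expect_equal(ident(tt), dist_survival(ref, tt))
  trt <- apply_hr(ref, 0.73)
  expect_equal(trt(9.8), 0.5^0.73, tolerance = 1e-12)
  expect_equal(trt(9.8), exp(0.73 * log(0.5)), tolerance = 1e-12)
  sq <- apply_hr(ref, 2)
  expect_equal(sq(tt), dist_survival(ref, tt)^2)
  expect_equal(sq(0), 1)
  expect_true(all(diff(sq(tt)) <= 0))
  expect_error(apply_hr(ref, 0), class = "psmcea_invalid_parameter")
})

test_that("tidiers expose parameters and fit statistics", {
  ipd <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 120, seed = 41)
  fit <- fit_parametric(ipd, "loglogistic")
  td <- tidy(fit)
  expect_named(td, c("family", "term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 120)
  expect_equal(gl$AIC, fit$aic)
})
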