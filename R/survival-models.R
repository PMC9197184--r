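flexsurv_dist_name <- function(family) {
  switch(family,
    exponential = "exp",
    weibull     = "weibull",
    lognormal   = "lnorm",
    loglogistic = "llogis",
    gompertz    = "gompertz")
}

# map a fitted flexsurv parameter vector back to this package's naming
flexsurv_to_spec <- function(family, res) {
  p <- setNames(res[, "est"], rownames(res))
  switch(family,
    exponential = dist_spec("exponential", rate = p[["rate"]]),
    weibull     = dist_spec("weibull", shape = p[["shape"]], scale = p[["scale"]]),
    lognormal   = dist_spec("lognormal", meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = dist_spec("loglogistic", scale = p[["scale"]], shape = p[["shape"]]),
    gompertz    = dist_spec("gompertz", shape = p[["shape"]], rate = p[["rate"]]))
}

#' Fit a parametric survival distribution to censored IPD
#'
#' Maximum-likelihood fit of one of the five supported families
#' (exponential, Weibull, log-normal, log-logistic, Gompertz) to
#' right-censored time-to-event data, maximising
#' \eqn{\sum_{events} \log h(t_i) + \sum_{all} \log S(t_i)}. Fitting is
#' delegated to [flexsurv::flexsurvreg()]; parameters are reported in this
#' package's conventions (see [dist_spec()]).
#'
#' @param ipd Tibble with `time_months`, `event`; at least 2 events.
#' @param family Family name, one of [dist_families()].
#' @return A `psm_fit`: list with `family`, `spec` (a [dist_spec()]),
#'   `params`, `loglik`, `aic` (`= 2 n_params - 2 loglik`), `n_params`,
#'   `n`, `n_events`.
#' @export
fit_parametric <- function(ipd, family) {
  check_ipd(ipd)
  family <- match.arg(family, dist_families())
  if (sum(ipd$event) < 2) {
    abort("need at least 2 events to fit a parametric model",
          class = "psmcea_invalid_input")
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time_months, event) ~ 1,
                          data = as.data.frame(ipd),
                          dist = flexsurv_dist_name(family)),
    error = function(e) {
      abort(sprintf("fit of family '%s' failed to converge: %s",
                    family, conditionMessage(e)),
            class = "psmcea_fit_error")
    })
  spec <- flexsurv_to_spec(family, fit$res)
  structure(list(
    family = family,
    spec = spec,
    params = spec$params,
    loglik = fit$loglik,
    n_params = fit$npars,
    aic = 2 * fit$npars - 2 * fit$loglik,
    n = nrow(ipd),
    n_events = sum(ipd$event)
  ), class = "psm_fit")
}

#' @export
print.psm_fit <- function(x, ...) {
  cat(sprintf("<psm_fit> %s: %s | loglik %.3f, AIC %.3f (n = %d, events = %d)\n",
              x$family,
              paste(sprintf("%s = %.5g", names(x$params), x$params), collapse = ", "),
              x$loglik, x$aic, x$n, x$n_events))
  invisible(x)
}

#' Fit all supported families and keep the results
#'
#' @param ipd Tibble with `time_months`, `event`.
#' @param families Character vector of families to try.
#' @return Named list of `psm_fit` objects (non-converging families are
#'   dropped with a warning).
#' @export
fit_all_families <- function(ipd, families = dist_families()) {
  fits <- list()
  for (f in families) {
    res <- tryCatch(fit_parametric(ipd, f), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("family '%s' dropped: %s", f, conditionMessage(res)))
    } else {
      fits[[f]] <- res
    }
  }
  fits
}

#' Select the best fit by minimum AIC
#'
#' Ties (AIC difference below `tol`) are broken by fewer parameters, then
#' by the fixed family order exponential, weibull, lognormal, loglogistic,
#' gompertz.
#'
#' @param fits List of `psm_fit` objects.
#' @param tol AIC tie tolerance.
#' @return The selected `psm_fit`.
#' @export
select_best <- function(fits, tol = 1e-9) {
  fits <- keep(fits, ~ inherits(.x, "psm_fit"))
  if (length(fits) == 0) abort("no converged fits supplied", class = "psmcea_empty_input")
  aics <- map_dbl(fits, "aic")
  npar <- map_dbl(fits, "n_params")
  fam_rank <- map_dbl(fits, ~ match(.x$family, dist_families()))
  best <- order(ifelse(aics - min(aics) <= tol, 0, 1), aics, npar, fam_rank)[1]
  fits[[best]]
}

#' Evaluate survival or hazard of a fitted model at given times
#'
#' @param fit A `psm_fit` or `dist_spec`.
#' @param t Times in months (>= 0).
#' @return Numeric vector of survival probabilities / hazard rates.
#' @export
survival_at <- function(fit, t) {
  dist_survival(as_dist_spec(fit), t)
}

#' @rdname survival_at
#' @export
hazard_at <- function(fit, t) {
  dist_hazard(as_dist_spec(fit), t)
}

as_dist_spec <- function(x) {
  if (inherits(x, "psm_fit")) return(x$spec)
  if (inherits(x, "dist_spec")) return(x)
  abort("expected a psm_fit or dist_spec", class = "psmcea_invalid_parameter")
}

#' @export
tidy.psm_fit <- function(x, ...) {
  tibble(family = x$family, term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.psm_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
         n_params = x$n_params, nobs = x$n, n_events = x$n_events)
}
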