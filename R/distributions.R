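#' Parametric survival distribution specification
#'
#' Container for one of the five parametric time-to-event families used
#' throughout the package. Times are in months. Parameterisations:
#' \describe{
#'   \item{exponential}{`rate` (events/month); S(t) = exp(-rate t)}
#'   \item{weibull}{`shape`, `scale`; S(t) = exp(-(t/scale)^shape)}
#'   \item{lognormal}{`meanlog`, `sdlog` on log-months}
#'   \item{loglogistic}{`scale` (alpha, the median), `shape` (k);
#'     S(t) = 1 / (1 + (t/scale)^shape)}
#'   \item{gompertz}{`shape` (any real), `rate` (> 0);
#'     H(t) = rate (exp(shape t) - 1) / shape}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`.
#' @param ... Named numeric parameters for the family (see Details).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("loglogistic", scale = 9.8, shape = 1.5)
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, dist_families())
  params <- c(...)
  need <- dist_param_names(family)
  if (!setequal(names(params), need)) {
    abort(sprintf("family '%s' needs parameters {%s}, got {%s}",
                  family, paste(need, collapse = ", "),
                  paste(names(params), collapse = ", ")),
          class = "psmcea_invalid_parameter")
  }
  params <- params[need]
  if (any(!is.finite(params))) {
    abort("distribution parameters must be finite", class = "psmcea_invalid_parameter")
  }
  # all parameters strictly positive except gompertz shape and lognormal meanlog
  free_sign <- switch(family, gompertz = "shape", lognormal = "meanlog", NULL)
  pos <- setdiff(need, free_sign)
  if (any(params[pos] <= 0)) {
    abort(sprintf("parameters {%s} must be > 0", paste(pos, collapse = ", ")),
          class = "psmcea_invalid_parameter")
  }
  structure(list(family = family, params = params), class = "dist_spec")
}

dist_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
}

dist_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("scale", "shape"),
    gompertz    = c("shape", "rate"))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

#' Calibrate a log-logistic distribution to a survival median
#'
#' Returns the log-logistic specification whose survival function passes
#' through 0.5 at the given median: under S(t) = 1 / (1 + (t/alpha)^k) the
#' scale alpha equals the median for any shape k.
#'
#' @param median Survival median in months (> 0).
#' @param shape Log-logistic shape k (> 0); larger k gives lighter tails.
#' @return A `dist_spec` of family `"loglogistic"`.
#' @examples
#' sp <- calibrate_loglogistic(9.8, 1.5)
#' dist_survival(sp, 9.8) # 0.5
#' @export
calibrate_loglogistic <- function(median, shape) {
  stop_if_not_scalar_pos(median, "median")
  stop_if_not_scalar_pos(shape, "shape")
  dist_spec("loglogistic", scale = median, shape = shape)
}

#' Survival, hazard and inverse-survival for a distribution spec
#'
#' Closed-form evaluators for the five supported families. `dist_survival`
#' gives S(t), `dist_hazard` the hazard h(t), and `dist_inv_survival` the
#' time at which survival equals `p`.
#'
#' @param spec A `dist_spec`.
#' @param t Time(s) in months, `>= 0`.
#' @param p Survival probability in (0, 1].
#' @return Numeric vector.
#' @export
dist_survival <- function(spec, t) {
  if (any(t < 0)) abort("t must be >= 0", class = "psmcea_invalid_parameter")
  p <- spec$params
  switch(spec$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-(t / p[["scale"]])^p[["shape"]]),
    lognormal   = plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    gompertz    = exp(-gompertz_cumhaz(t, p[["shape"]], p[["rate"]])))
}

gompertz_cumhaz <- function(t, shape, rate) {
  if (abs(shape) < 1e-12) rate * t else rate * expm1(shape * t) / shape
}

#' @rdname dist_survival
#' @export
dist_hazard <- function(spec, t) {
  if (any(t < 0)) abort("t must be >= 0", class = "psmcea_invalid_parameter")
  p <- spec$params
  switch(spec$family,
    exponential = rep_len(p[["rate"]], length(t)),
    weibull     = p[["shape"]] / p[["scale"]] * (t / p[["scale"]])^(p[["shape"]] - 1),
    lognormal   = dlnorm(t, p[["meanlog"]], p[["sdlog"]]) /
                    plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = {
      k <- p[["shape"]]; a <- p[["scale"]]
      (k / a) * (t / a)^(k - 1) / (1 + (t / a)^k)
    },
    gompertz    = p[["rate"]] * exp(p[["shape"]] * t))
}

#' @rdname dist_survival
#' @export
dist_inv_survival <- function(spec, p) {
  if (any(p <= 0 | p > 1)) {
    abort("p must be in (0, 1]", class = "psmcea_invalid_parameter")
  }
  pr <- spec$params
  switch(spec$family,
    exponential = -log(p) / pr[["rate"]],
    weibull     = pr[["scale"]] * (-log(p))^(1 / pr[["shape"]]),
    lognormal   = exp(pr[["meanlog"]] + pr[["sdlog"]] * qnorm(1 - p)),
    loglogistic = pr[["scale"]] * (1 / p - 1)^(1 / pr[["shape"]]),
    gompertz    = {
      a <- pr[["shape"]]; b <- pr[["rate"]]; H <- -log(p)
      if (abs(a) < 1e-12) H / b else log1p(a * H / b) / a
    })
}

#' Coerce fits, specs or functions to a survival-curve function of months
#'
#' @param x A `dist_spec`, `psm_fit`, or a function of time in months.
#' @return A vectorised function `S(t_months)`.
#' @export
as_surv_fn <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "psm_fit")) x <- x$spec
  if (!inherits(x, "dist_spec")) {
    abort("expected a dist_spec, psm_fit or function", class = "psmcea_invalid_parameter")
  }
  force(x)
  function(t) dist_survival(x, t)
}

#' Transform a survival curve by a hazard ratio
#'
#' Under proportional hazards on the cumulative hazard scale, the
#' comparator curve is `S_ref(t)^hr`: hazard ratios below 1 shift survival
#' upward (longer survival).
#'
#' @param reference A `dist_spec`, `psm_fit` or survival function S(t).
#' @param hr Hazard ratio (> 0).
#' @return A function `S_adj(t_months)`.
#' @examples
#' ctrl <- calibrate_loglogistic(9.8, 1.5)
#' trt <- apply_hr(ctrl, 0.73)
#' trt(9.8) # 0.5^0.73
#' @export
apply_hr <- function(reference, hr) {
  stop_if_not_scalar_pos(hr, "hr")
  s_ref <- as_surv_fn(reference)
  function(t) s_ref(t)^hr
}
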