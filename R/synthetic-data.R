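#' Censoring specification for simulated trial arms
#'
#' @param admin_cutoff Administrative censoring time in months (> 0, may be
#'   `Inf`). Default 22.6 months, a typical immunotherapy-trial median
#'   follow-up.
#' @param dropout_rate Constant per-month dropout hazard (>= 0).
#' @return An object of class `censor_spec`.
#' @export
censor_spec <- function(admin_cutoff = 22.6, dropout_rate = 0.01) {
  if (!is.numeric(admin_cutoff) || length(admin_cutoff) != 1L ||
      is.na(admin_cutoff) || admin_cutoff <= 0) {
    abort("`admin_cutoff` must be a single positive number (Inf allowed)",
          class = "psmcea_invalid_parameter")
  }
  stop_if_not_scalar_pos(dropout_rate, "dropout_rate", strict = FALSE)
  structure(list(admin_cutoff = admin_cutoff, dropout_rate = dropout_rate),
            class = "censor_spec")
}

#' Simulate censored individual-patient time-to-event data
#'
#' Event times are drawn from `spec` by inverse-survival sampling; an
#' optional hazard ratio `hr` draws times from the curve `S(t)^hr` instead,
#' which is how the intervention arm of a two-arm trial is generated from
#' the control-arm distribution. Observed time is the minimum of the event
#' time, an exponential dropout time and the administrative cutoff; the
#' event flag is 1 iff the event time is the minimum.
#'
#' @param spec A `dist_spec` for the event-time distribution.
#' @param censor A `censor_spec`; use
#'   `censor_spec(Inf, 0)` for no censoring.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; simulation is reproducible for a fixed seed.
#' @param hr Hazard ratio applied to the event-time survival curve
#'   (default 1 = sample from `spec` itself).
#' @return A tibble with columns `time_months` (> 0) and `event` (0/1).
#' @examples
#' sp <- calibrate_loglogistic(9.8, 1.5)
#' ipd <- simulate_ipd(sp, censor_spec(), n = 374, seed = 1)
#' @export
simulate_ipd <- function(spec, censor = censor_spec(), n, seed, hr = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer", class = "psmcea_invalid_parameter")
  }
  stop_if_not_scalar_pos(hr, "hr")
  withr_seed(seed, {
    u <- runif(n)
    # S_arm(t) = S_spec(t)^hr  =>  t = S_spec^{-1}(u^{1/hr})
    t_event <- vapply(u^(1 / hr), function(p) dist_inv_survival(spec, p), numeric(1))
    t_drop <- if (censor$dropout_rate > 0) rexp(n, censor$dropout_rate) else rep(Inf, n)
    time <- pmin(t_event, t_drop, censor$admin_cutoff)
    event <- as.integer(t_event <= pmin(t_drop, censor$admin_cutoff))
    tibble(time_months = pmax(time, 1e-9), event = event)
  })
}

# evaluate `code` under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Produce digitized-curve and risk-table artifacts from IPD
#'
#' Emulates what curve digitization of a published Kaplan-Meier plot plus
#' its number-at-risk table would yield: the product-limit estimate sampled
#' on a regular time grid (step-function convention) and at-risk counts at
#' regular interval boundaries.
#'
#' @param ipd Tibble with `time_months`, `event`.
#' @param grid_step Curve sampling step in months (> 0).
#' @param risk_interval Risk-table spacing in months (> 0).
#' @return A list with tibbles `curve` (`time_months`, `survival`) and
#'   `risk` (`time_months`, `n_at_risk`).
#' @export
make_km_artifacts <- function(ipd, grid_step = 0.25, risk_interval = 3) {
  check_ipd(ipd)
  stop_if_not_scalar_pos(grid_step, "grid_step")
  stop_if_not_scalar_pos(risk_interval, "risk_interval")
  km <- km_estimate(ipd)
  t_max <- max(ipd$time_months)
  grid <- seq(0, t_max, by = grid_step)
  sfun <- stats::stepfun(km$time_months, c(1, km$survival), right = FALSE)
  risk_t <- seq(0, t_max, by = risk_interval)
  list(
    curve = tibble(time_months = grid, survival = sfun(grid)),
    risk = tibble(time_months = risk_t,
                  n_at_risk = vapply(risk_t, function(b) sum(ipd$time_months >= b), integer(1)))
  )
}

#' Build a Gompertz-Makeham annual life table
#'
#' Annual death probability `q_annual(age) = 1 - exp(-(a + b c^age))`,
#' clipped to `[0, 1]`, with the terminal age forced to `q = 1`. The
#' defaults give adult mortality of the magnitude seen in recent East-Asian
#' national life tables (e.g. q(63) around 0.012); the default terminal age 105
#' covers a 30-year horizon from any plausible trial entry age.
#'
#' @param a Makeham age-independent hazard term (>= 0).
#' @param b Gompertz baseline hazard (> 0).
#' @param c Gompertz rate of ageing (> 0, typically 1.08-1.11).
#' @param max_age Terminal age (<= 120).
#' @return A tibble with columns `age`, `q_annual`.
#' @export
make_life_table <- function(a = 0.001, b = 5e-5, c = 1.09, max_age = 105) {
  stop_if_not_scalar_pos(a, "a", strict = FALSE)
  stop_if_not_scalar_pos(b, "b")
  stop_if_not_scalar_pos(c, "c")
  if (max_age > 120 || max_age < 1) {
    abort("`max_age` must be in [1, 120]", class = "psmcea_invalid_parameter")
  }
  age <- 0:max_age
  q <- 1 - exp(-(a + b * c^age))
  if (any(is.nan(q))) abort("life-table parameters produced NaN", class = "psmcea_invalid_parameter")
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  tibble(age = age, q_annual = q)
}

check_life_table <- function(lt) {
  if (!all(c("age", "q_annual") %in% names(lt)) || nrow(lt) < 1) {
    abort("life table needs columns age, q_annual", class = "psmcea_invalid_input")
  }
  if (any(diff(lt$age) != 1)) abort("life-table ages must be contiguous", class = "psmcea_invalid_input")
  if (any(lt$q_annual < 0 | lt$q_annual > 1)) {
    abort("q_annual must be in [0, 1]", class = "psmcea_invalid_input")
  }
  invisible(lt)
}

#' Generate a full synthetic two-arm trial fixture set
#'
#' Draws control-arm overall-survival (OS) and progression-free-survival
#' (PFS) times from log-logistic distributions calibrated to the given
#' medians, and intervention-arm times from the control curves raised to
#' the power of the hazard ratios (`S_trt = S_ctrl^HR`). OS and PFS are
#' simulated independently per endpoint: the downstream partitioned-survival
#' model consumes marginal curves only. Returns the per-arm IPD together
#' with digitized-curve and risk-table artifacts for all four
#' arm-by-endpoint combinations, and a life table.
#'
#' @param n_per_arm Subjects per arm.
#' @param os_median,pfs_median Control-arm medians in months.
#' @param os_shape,pfs_shape Log-logistic shapes for the control curves.
#' @param hr_os,hr_pfs Intervention vs control hazard ratios.
#' @param censor A `censor_spec` shared by both arms and endpoints.
#' @param seed Master seed for the generator.
#' @return A list with elements `ipd` (named list of four tibbles:
#'   `ctrl_os`, `ctrl_pfs`, `trt_os`, `trt_pfs`), `artifacts` (same names;
#'   each a `curve`/`risk` pair), `life_table`, and `specs`.
#' @export
synth_trial <- function(n_per_arm = 374,
                        os_median = 9.8, pfs_median = 5.8,
                        os_shape = 1.5, pfs_shape = 1.6,
                        hr_os = 0.73, hr_pfs = 0.65,
                        censor = censor_spec(), seed = 2020) {
  specs <- list(os = calibrate_loglogistic(os_median, os_shape),
                pfs = calibrate_loglogistic(pfs_median, pfs_shape))
  seed <- as.integer(seed) %% .Machine$integer.max
  ipd <- list(
    ctrl_os  = simulate_ipd(specs$os, censor, n_per_arm, seed + 1L),
    ctrl_pfs = simulate_ipd(specs$pfs, censor, n_per_arm, seed + 2L),
    trt_os   = simulate_ipd(specs$os, censor, n_per_arm, seed + 3L, hr = hr_os),
    trt_pfs  = simulate_ipd(specs$pfs, censor, n_per_arm, seed + 4L, hr = hr_pfs)
  )
  artifacts <- map(ipd, make_km_artifacts)
  list(ipd = ipd, artifacts = artifacts, life_table = make_life_table(),
       specs = specs, hr = c(os = hr_os, pfs = hr_pfs))
}
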