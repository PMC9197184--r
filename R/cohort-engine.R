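#' Cohort-model settings
#'
#' @param cycle_days Cycle length in days (default 21, a 3-week treatment
#'   cycle).
#' @param discount_annual Annual discount rate applied to both costs and
#'   effects (default 0.03; one-way bounds 0-0.05).
#' @param start_age Cohort age in years at model entry (default 63).
#' @param horizon_years Time horizon (default 30 years, effectively
#'   lifetime for this population).
#' @param wtp Willingness-to-pay threshold in $/QALY (default 31304.31,
#'   three times Chinese per-capita GDP).
#' @return A `model_settings` list.
#' @export
model_settings <- function(cycle_days = 21, discount_annual = 0.03,
                           start_age = 63, horizon_years = 30,
                           wtp = 31304.31) {
  stop_if_not_scalar_pos(cycle_days, "cycle_days")
  if (discount_annual < 0 || discount_annual > 0.10) {
    abort("`discount_annual` must be in [0, 0.10]", class = "psmcea_invalid_parameter")
  }
  stop_if_not_scalar_pos(start_age, "start_age")
  stop_if_not_scalar_pos(horizon_years, "horizon_years")
  stop_if_not_scalar_pos(wtp, "wtp")
  structure(list(cycle_days = cycle_days, discount_annual = discount_annual,
                 start_age = start_age, horizon_years = horizon_years,
                 wtp = wtp),
            class = "model_settings")
}

cycle_years <- function(settings) settings$cycle_days / DAYS_PER_YEAR
cycle_months <- function(settings) settings$cycle_days / DAYS_PER_MONTH

#' Discount factor at a model cycle
#'
#' `(1 + r)^(-t)` with `t` the cycle start time in years.
#'
#' @param cycle Cycle index (vectorised, >= 0).
#' @param settings A [model_settings()].
#' @return Numeric vector of factors in (0, 1].
#' @export
discount_factor <- function(cycle, settings) {
  (1 + settings$discount_annual)^(-(cycle * cycle_years(settings)))
}

#' Half-cycle correction of a per-cycle series
#'
#' Trapezoid rule on cycle boundaries: the corrected value for interval c
#' is the mean of the boundary values, so state membership is credited as
#' of mid-cycle. Output has one fewer element than the input.
#'
#' @param values Numeric series sampled at cycle boundaries (length >= 2).
#' @return Numeric vector of length `length(values) - 1`.
#' @export
half_cycle_correct <- function(values) {
  n <- length(values)
  if (n < 2) abort("need at least 2 cycle values", class = "psmcea_invalid_input")
  (values[-n] + values[-1]) / 2
}

#' Build a partitioned-survival cohort trace
#'
#' State occupancy is read off the overall-survival (OS) and
#' progression-free-survival (PFS) curves: `pfs = min(PFS, OS*)`,
#' `dead = 1 - OS*`, `pd = OS* - pfs`, where `OS*` compounds per-cycle
#' death probabilities floored by age-specific background mortality from
#' the life table (the model never predicts less death than the general
#' population at the cohort's current age).
#'
#' @param os_curve,pfs_curve Survival curves: `dist_spec`, `psm_fit` or a
#'   function of time in months.
#' @param life_table Tibble `age`, `q_annual` (see [make_life_table()]).
#' @param settings A [model_settings()].
#' @return A `psm_trace` tibble with columns `cycle`, `time_years`, `age`,
#'   `pfs`, `pd`, `dead`; rows sum to 1. The trace is truncated once fewer
#'   than 1e-6 of the cohort remains alive.
#' @export
build_trace <- function(os_curve, pfs_curve, life_table, settings = model_settings()) {
  check_life_table(life_table)
  s_os <- as_surv_fn(os_curve)
  s_pfs <- as_surv_fn(pfs_curve)
  n_cycles <- floor(settings$horizon_years * DAYS_PER_YEAR / settings$cycle_days)
  cyc <- 0:n_cycles
  t_months <- cyc * cycle_months(settings)
  t_years <- cyc * cycle_years(settings)
  age <- settings$start_age + t_years

  idx <- match(floor(age[-length(age)]), life_table$age)
  if (any(is.na(idx))) {
    abort("cohort age leaves the life-table range over the model horizon",
          class = "psmcea_invalid_input")
  }
  q_ann <- life_table$q_annual[idx]
  p_bg <- 1 - (1 - q_ann)^cycle_years(settings)   # per-cycle background death

  os_raw <- s_os(t_months)
  p_model <- ifelse(os_raw[-length(os_raw)] > 0,
                    pmin(pmax(1 - os_raw[-1] / os_raw[-length(os_raw)], 0), 1), 1)
  p_death <- pmax(p_model, p_bg)
  os_star <- cumprod(c(1, 1 - p_death))

  pfs_occ <- pmin(s_pfs(t_months), os_star)
  dead <- 1 - os_star
  pd <- pmax(os_star - pfs_occ, 0)

  keep_until <- which(dead > 1 - 1e-6)[1]
  if (!is.na(keep_until)) {
    sel <- seq_len(keep_until)
  } else {
    sel <- seq_along(cyc)
  }
  out <- tibble(cycle = cyc[sel], time_years = t_years[sel], age = age[sel],
                pfs = pfs_occ[sel], pd = pd[sel], dead = dead[sel])
  structure(out, class = c("psm_trace", class(out)), settings = settings)
}

#' Discounted (or raw) life years from a trace
#'
#' Sums half-cycle-corrected alive occupancy over cycles, weighted by the
#' discount factor at each interval's starting cycle.
#'
#' @param trace A `psm_trace`.
#' @param settings A [model_settings()]; defaults to the trace's own.
#' @param discounted Apply discounting? (default `TRUE`).
#' @return Life years (scalar).
#' @export
life_years <- function(trace, settings = attr(trace, "settings"), discounted = TRUE) {
  alive <- trace$pfs + trace$pd
  hcc <- half_cycle_correct(alive)
  disc <- if (discounted) discount_factor(trace$cycle[-nrow(trace)], settings) else 1
  sum(hcc * disc) * cycle_years(settings)
}

#' @export
print.psm_trace <- function(x, ...) {
  cat(sprintf("<psm_trace> %d cycles over %.1f years; final dead = %.6f\n",
              nrow(x) - 1, max(x$time_years), x$dead[nrow(x)]))
  NextMethod()
}
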