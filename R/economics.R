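#' Default cost inputs (2020 USD)
#'
#' Per-cycle drug acquisition and administration costs with one-way bounds:
#' drug and administration costs carry either their source's range or
#' +/-20% of base; the pembrolizumab price is varied +/-50% in sensitivity
#' analysis.
#'
#' @return Tibble with columns `item`, `base`, `low`, `high`.
#' @export
cost_inputs <- function() {
  tibble::tribble(
    ~item,               ~base,    ~low,     ~high,
    "pembrolizumab",     5625.75,  2812.87,  8438.62,
    "fluorouracil",      256.67,   205.34,   308.01,
    "cisplatin",         17.52,    14.01,    21.02,
    "paclitaxel",        351.81,   281.44,   422.17,
    "routine_followup",  55.18,    44.14,    66.21,
    "supportive_care",   125.47,   100.37,   150.56,
    "ae_nausea",         71.00,    56.80,    85.20,
    "ae_anaemia",        73.68,    58.94,    88.42,
    "ae_neutrophil",     466.00,   372.80,   559.20,
    "ae_neutropenia",    466.00,   372.80,   559.20,
    "ae_wbc",            466.00,   372.80,   559.20
  )
}

#' Default health-state utilities
#'
#' @return Tibble with `state`, `base`, `low`, `high`: progression-free
#'   0.74 (0.59-0.89), progressed disease 0.58 (0.46-0.70); dead is 0.
#' @export
utility_inputs <- function() {
  tibble::tribble(
    ~state, ~base, ~low, ~high,
    "pfs",  0.74,  0.59, 0.89,
    "pd",   0.58,  0.46, 0.70
  )
}

#' Default grade >= 3 adverse-event profile (synthetic incidences)
#'
#' Unit management costs per event are source values; the per-arm
#' incidences are synthetic defaults of realistic magnitude for a
#' platinum/fluoropyrimidine backbone with or without a PD-1 inhibitor —
#' they are not trial-reported numbers and should be overridden with the
#' user's own data where available (see
#' `inst/extdata/ae_profile_synthetic.csv`).
#'
#' @return Tibble `ae`, `cost_per_event`, `incidence_trt`, `incidence_ctrl`.
#' @export
ae_profile <- function() {
  tibble::tribble(
    ~ae,             ~cost_per_event, ~incidence_trt, ~incidence_ctrl,
    "nausea",        71.00,           0.07,           0.06,
    "anaemia",       73.68,           0.12,           0.10,
    "neutrophil",    466.00,          0.14,           0.12,
    "neutropenia",   466.00,          0.07,           0.08,
    "wbc",           466.00,          0.08,           0.07
  )
}

#' Define a treatment regimen line
#'
#' One drug (or care component) priced per model cycle, applied to the
#' occupancy of one health state, optionally capped at a maximum number of
#' cycles and weighted by an uptake fraction.
#'
#' @param drug Name.
#' @param cost_per_cycle $ per cycle (>= 0).
#' @param max_cycles Cap on treatment cycles (`Inf` = until progression /
#'   death).
#' @param state `"pfs"` or `"pd"` — the occupancy the cost multiplies.
#' @param uptake_fraction Fraction of the state occupancy treated.
#' @return One-row tibble.
#' @export
regimen_line <- function(drug, cost_per_cycle, max_cycles = Inf,
                         state = c("pfs", "pd"), uptake_fraction = 1) {
  state <- match.arg(state)
  stop_if_not_scalar_pos(cost_per_cycle, "cost_per_cycle", strict = FALSE)
  if (uptake_fraction < 0 || uptake_fraction > 1) {
    abort("`uptake_fraction` must be in [0, 1]", class = "psmcea_invalid_parameter")
  }
  if (!(is.infinite(max_cycles) || (max_cycles >= 1 && max_cycles == round(max_cycles)))) {
    abort("`max_cycles` must be a positive integer or Inf", class = "psmcea_invalid_parameter")
  }
  tibble(drug = drug, cost_per_cycle = cost_per_cycle, max_cycles = max_cycles,
         state = state, uptake_fraction = uptake_fraction)
}

#' Default regimens for the two strategies
#'
#' First line: pembrolizumab 200 mg q3w up to 35 cycles (intervention arm
#' only) plus a 5-fluorouracil + cisplatin backbone capped at 6 cycles in
#' both arms. Second line: paclitaxel while in progressed disease, taken
#' up by 43% (intervention) / 47% (control) of progressing patients.
#'
#' @param costs A [cost_inputs()]-shaped tibble (values may be modified).
#' @param uptake_trt,uptake_ctrl Second-line uptake fractions.
#' @param pembro_cap,chemo_cap Cycle caps.
#' @return Named list of regimen tibbles: `trt`, `ctrl`.
#' @export
default_regimens <- function(costs = cost_inputs(),
                             uptake_trt = 0.43, uptake_ctrl = 0.47,
                             pembro_cap = 35, chemo_cap = 6) {
  cost_of <- function(item) costs$base[match(item, costs$item)]
  backbone <- bind_rows(
    regimen_line("fluorouracil", cost_of("fluorouracil"), chemo_cap, "pfs"),
    regimen_line("cisplatin", cost_of("cisplatin"), chemo_cap, "pfs")
  )
  list(
    trt = bind_rows(
      regimen_line("pembrolizumab", cost_of("pembrolizumab"), pembro_cap, "pfs"),
      backbone,
      regimen_line("paclitaxel", cost_of("paclitaxel"), Inf, "pd", uptake_trt)
    ),
    ctrl = bind_rows(
      backbone,
      regimen_line("paclitaxel", cost_of("paclitaxel"), Inf, "pd", uptake_ctrl)
    )
  )
}

#' Per-cycle drug cost series for one regimen line
#'
#' Drugs are dispensed at cycle start, so the cost multiplies the
#' uncorrected (start-of-cycle) state occupancy; cycles at or beyond
#' `max_cycles` cost nothing.
#'
#' @param line A [regimen_line()] row.
#' @param trace A `psm_trace`.
#' @return Numeric vector, one undiscounted $ amount per trace cycle.
#' @export
drug_cost_vector <- function(line, trace) {
  if (!line$state %in% c("pfs", "pd")) {
    abort(sprintf("unknown state label '%s'", line$state), class = "psmcea_invalid_parameter")
  }
  occ <- trace[[line$state]]
  on_treatment <- as.numeric(trace$cycle < line$max_cycles)
  line$cost_per_cycle * occ * line$uptake_fraction * on_treatment
}

#' Lump adverse-event management cost at model entry
#'
#' Sum over events of incidence times unit management cost, charged at
#' cycle 0 (discount factor 1).
#'
#' @param profile An [ae_profile()]-shaped tibble.
#' @param arm `"trt"` or `"ctrl"` — selects the incidence column.
#' @return Scalar $ amount.
#' @export
ae_lump_cost <- function(profile, arm = c("trt", "ctrl")) {
  arm <- match.arg(arm)
  inc <- profile[[paste0("incidence_", arm)]]
  if (any(inc < 0 | inc > 1)) abort("AE incidences must be in [0, 1]",
                                    class = "psmcea_invalid_parameter")
  sum(inc * profile$cost_per_event)
}

#' Accrue discounted cost, life years and QALYs over a trace
#'
#' Utilities and continuous care costs (routine follow-up in PFS,
#' supportive care in PD) accrue continuously and are half-cycle
#' corrected; drug acquisition costs use start-of-cycle occupancy.
#'
#' @param trace A `psm_trace`.
#' @param regimen Tibble of [regimen_line()] rows for this strategy.
#' @param costs [cost_inputs()]-shaped tibble (for follow-up / supportive
#'   care rates).
#' @param utilities [utility_inputs()]-shaped tibble.
#' @param settings A [model_settings()]; defaults to the trace's.
#' @param ae [ae_profile()]-shaped tibble, or `NULL` for no AE cost.
#' @param arm Which AE incidence column applies.
#' @param strategy Label for the output row.
#' @return One-row tibble: `strategy`, `cost`, `ly`, `qaly` (discounted).
#' @export
accrue <- function(trace, regimen, costs = cost_inputs(),
                   utilities = utility_inputs(),
                   settings = attr(trace, "settings"),
                   ae = ae_profile(), arm = c("trt", "ctrl"),
                   strategy = arm) {
  arm <- match.arg(arm)
  n <- nrow(trace)
  disc_all <- discount_factor(trace$cycle, settings)
  disc_int <- disc_all[-n]

  u <- setNames(utilities$base, utilities$state)
  qaly <- sum(half_cycle_correct(u[["pfs"]] * trace$pfs + u[["pd"]] * trace$pd) *
                disc_int) * cycle_years(settings)
  ly <- life_years(trace, settings)

  drug_cost <- 0
  for (i in seq_len(nrow(regimen))) {
    drug_cost <- drug_cost + sum(drug_cost_vector(regimen[i, ], trace) * disc_all)
  }
  rate_of <- function(item) costs$base[match(item, costs$item)]
  care_cost <- sum(half_cycle_correct(trace$pfs) * disc_int) * rate_of("routine_followup") +
    sum(half_cycle_correct(trace$pd) * disc_int) * rate_of("supportive_care")
  ae_cost <- if (is.null(ae)) 0 else ae_lump_cost(ae, arm)

  tibble(strategy = strategy[1], cost = drug_cost + care_cost + ae_cost,
         ly = ly, qaly = qaly)
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' @param trt,ctrl One-row tibbles from [accrue()]; `trt` is the
#'   comparator of interest, `ctrl` the reference.
#' @param wtp Willingness-to-pay threshold used for labelling only.
#' @return A `psm_ce` object: per-strategy totals plus `delta_cost`,
#'   `delta_ly`, `delta_qaly`, `icer` ($/QALY), `icer_per_ly` ($/LY) and a
#'   `status` label (`"icer"`, `"dominant"`, `"dominated"`,
#'   `"non-comparable"`).
#' @export
icer <- function(trt, ctrl, wtp = NULL) {
  d_cost <- trt$cost - ctrl$cost
  d_ly <- trt$ly - ctrl$ly
  d_qaly <- trt$qaly - ctrl$qaly
  status <- if (abs(d_qaly) < 1e-12) {
    if (abs(d_cost) < 1e-9) "non-comparable" else "non-comparable"
  } else if (d_cost < 0 && d_qaly > 0) "dominant"
  else if (d_cost > 0 && d_qaly < 0) "dominated"
  else "icer"
  ratio <- if (status == "icer") d_cost / d_qaly else if (status == "non-comparable") Inf else NA_real_
  structure(list(
    strategies = bind_rows(trt, ctrl),
    delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
    icer = ratio,
    icer_per_ly = if (abs(d_ly) > 1e-12) d_cost / d_ly else NA_real_,
    status = status, wtp = wtp
  ), class = "psm_ce")
}

#' @export
print.psm_ce <- function(x, ...) {
  cat("<psm_ce> incremental cost-effectiveness\n")
  print(as.data.frame(x$strategies), row.names = FALSE)
  cat(sprintf("  delta cost $%.2f | delta LY %.4f | delta QALY %.4f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  if (x$status == "icer") {
    cat(sprintf("  ICER $%.2f/QALY ($%.2f/LY)\n", x$icer, x$icer_per_ly))
  } else {
    cat(sprintf("  status: %s\n", x$status))
  }
  if (!is.null(x$wtp)) {
    verdict <- if (x$status == "dominant" ||
                   (x$status == "icer" && x$icer <= x$wtp)) "cost-effective"
               else "NOT cost-effective"
    cat(sprintf("  at WTP $%.2f/QALY: %s\n", x$wtp, verdict))
  }
  invisible(x)
}

#' @export
tidy.psm_ce <- function(x, ...) {
  x$strategies
}

#' @export
glance.psm_ce <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_ly = x$delta_ly,
         delta_qaly = x$delta_qaly, icer = x$icer,
         icer_per_ly = x$icer_per_ly, status = x$status,
         wtp = x$wtp %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
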