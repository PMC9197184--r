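#' Assemble a cost-effectiveness model configuration
#'
#' Binds together everything one deterministic model evaluation needs:
#' control-arm survival fits, the hazard ratios that drive the
#' intervention arm (`S_trt = S_ctrl^HR`), the life table, model settings
#' and economic inputs. All sensitivity analyses rerun this object with
#' parameters overridden.
#'
#' @param os_fit,pfs_fit Control-arm curves (`psm_fit`, `dist_spec` or
#'   function of months).
#' @param hr_os,hr_pfs Intervention vs control hazard ratios.
#' @param life_table Tibble `age`, `q_annual`.
#' @param settings A [model_settings()].
#' @param costs,utilities,ae Economic input tibbles.
#' @param uptake_trt,uptake_ctrl Second-line uptake fractions.
#' @param pembro_cap,chemo_cap Treatment cycle caps.
#' @param trt_os_fit,trt_pfs_fit Optional directly fitted intervention-arm
#'   curves; when supplied they replace the HR transformation in the base
#'   case (HRs still drive sensitivity analyses).
#' @return A `ce_config` list.
#' @export
ce_config <- function(os_fit, pfs_fit, hr_os = 0.73, hr_pfs = 0.65,
                      life_table = make_life_table(),
                      settings = model_settings(),
                      costs = cost_inputs(), utilities = utility_inputs(),
                      ae = ae_profile(),
                      uptake_trt = 0.43, uptake_ctrl = 0.47,
                      pembro_cap = 35, chemo_cap = 6,
                      trt_os_fit = NULL, trt_pfs_fit = NULL) {
  stop_if_not_scalar_pos(hr_os, "hr_os")
  stop_if_not_scalar_pos(hr_pfs, "hr_pfs")
  structure(list(os_fit = os_fit, pfs_fit = pfs_fit,
                 hr_os = hr_os, hr_pfs = hr_pfs,
                 life_table = life_table, settings = settings,
                 costs = costs, utilities = utilities, ae = ae,
                 uptake_trt = uptake_trt, uptake_ctrl = uptake_ctrl,
                 pembro_cap = pembro_cap, chemo_cap = chemo_cap,
                 trt_os_fit = trt_os_fit, trt_pfs_fit = trt_pfs_fit),
            class = "ce_config")
}

#' Sensitivity-analysis parameter space
#'
#' One row per tunable parameter with base value, one-way bounds, the
#' probabilistic distribution family and its role. Utilities draw from
#' beta distributions, costs from gamma, hazard ratios from lognormal
#' (from their 95% CIs); the discount rate and cohort start age enter the
#' one-way analysis only.
#'
#' @param config A [ce_config()] (bounds for HRs/costs/utilities are read
#'   from it).
#' @param start_age_bounds Low/high bounds for the cohort entry age.
#' @return Tibble `param`, `base`, `low`, `high`, `dist`, `role`.
#' @export
param_space <- function(config, start_age_bounds = c(53, 73)) {
  costs <- config$costs |>
    mutate(param = paste0("cost_", .data$item), dist = "gamma", role = "cost") |>
    select("param", "base", "low", "high", "dist", "role")
  utils_ <- config$utilities |>
    mutate(param = paste0("u_", .data$state), dist = "beta", role = "utility") |>
    select("param", "base", "low", "high", "dist", "role")
  bind_rows(
    tibble(param = c("hr_os", "hr_pfs"),
           base = c(config$hr_os, config$hr_pfs),
           low = c(0.58, 0.52), high = c(0.88, 0.78),
           dist = "lognormal", role = "hr"),
    costs, utils_,
    tibble(param = "discount", base = config$settings$discount_annual,
           low = 0, high = 0.05, dist = "fixed", role = "rate"),
    tibble(param = "start_age", base = config$settings$start_age,
           low = start_age_bounds[1], high = start_age_bounds[2],
           dist = "fixed", role = "age")
  )
}

# apply named overrides to a config, returning the modified config
override_config <- function(config, overrides) {
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (nm %in% c("hr_os", "hr_pfs")) {
      config[[nm]] <- val
    } else if (nm == "discount") {
      config$settings$discount_annual <- val
    } else if (nm == "start_age") {
      config$settings$start_age <- val
    } else if (startsWith(nm, "cost_")) {
      item <- sub("^cost_", "", nm)
      i <- match(item, config$costs$item)
      if (is.na(i)) abort(sprintf("unknown cost parameter '%s'", nm),
                          class = "psmcea_invalid_parameter")
      config$costs$base[i] <- val
    } else if (startsWith(nm, "u_")) {
      st <- sub("^u_", "", nm)
      i <- match(st, config$utilities$state)
      if (is.na(i)) abort(sprintf("unknown utility parameter '%s'", nm),
                          class = "psmcea_invalid_parameter")
      config$utilities$base[i] <- val
    } else {
      abort(sprintf("parameter '%s' is not in the model", nm),
            class = "psmcea_invalid_parameter")
    }
  }
  config
}

# AE profile with unit costs taken from the (possibly overridden) cost table
ae_with_costs <- function(ae, costs) {
  i <- match(paste0("ae_", ae$ae), costs$item)
  ae$cost_per_event <- ifelse(is.na(i), ae$cost_per_event, costs$base[i])
  ae
}

#' Run the deterministic model for one parameter configuration
#'
#' @param config A [ce_config()].
#' @param overrides Named list/vector of parameter overrides (names as in
#'   [param_space()]).
#' @param use_direct_fits Use directly fitted intervention-arm curves when
#'   present instead of the HR transformation.
#' @return A `psm_ce`.
#' @export
run_model <- function(config, overrides = NULL, use_direct_fits = FALSE) {
  if (length(overrides)) config <- override_config(config, as.list(overrides))
  st <- config$settings
  ctrl_os <- as_surv_fn(config$os_fit)
  ctrl_pfs <- as_surv_fn(config$pfs_fit)
  if (use_direct_fits && !is.null(config$trt_os_fit)) {
    trt_os <- as_surv_fn(config$trt_os_fit)
    trt_pfs <- as_surv_fn(config$trt_pfs_fit)
  } else {
    trt_os <- apply_hr(config$os_fit, config$hr_os)
    trt_pfs <- apply_hr(config$pfs_fit, config$hr_pfs)
  }
  tr_trt <- build_trace(trt_os, trt_pfs, config$life_table, st)
  tr_ctrl <- build_trace(ctrl_os, ctrl_pfs, config$life_table, st)
  reg <- default_regimens(config$costs, config$uptake_trt, config$uptake_ctrl,
                          config$pembro_cap, config$chemo_cap)
  ae <- ae_with_costs(config$ae, config$costs)
  res_trt <- accrue(tr_trt, reg$trt, config$costs, config$utilities, st, ae,
                    "trt", "pembrolizumab + chemotherapy")
  res_ctrl <- accrue(tr_ctrl, reg$ctrl, config$costs, config$utilities, st, ae,
                     "ctrl", "placebo + chemotherapy")
  icer(res_trt, res_ctrl, wtp = st$wtp)
}

#' Base-case analysis
#'
#' @param config A [ce_config()].
#' @return A `psm_ce` at base parameter values.
#' @export
run_base_case <- function(config) run_model(config)

#' One-way (tornado) sensitivity analysis
#'
#' Each parameter is set to its low and high bound in turn with all others
#' held at base; rows are sorted by ICER spread, the tornado ordering.
#'
#' @param config A [ce_config()].
#' @param space A [param_space()] tibble.
#' @return Tibble `parameter`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `spread`, sorted by `spread` descending, with the
#'   base-case ICER attached as attribute `icer_base`.
#' @export
one_way <- function(config, space = param_space(config)) {
  base_ce <- run_base_case(config)
  rows <- pmap(space, function(param, base, low, high, dist, role) {
    i_lo <- run_model(config, setNames(list(low), param))
    i_hi <- run_model(config, setNames(list(high), param))
    tibble(parameter = param, low = low, high = high,
           icer_at_low = i_lo$icer, icer_at_high = i_hi$icer)
  })
  out <- bind_rows(rows) |>
    mutate(spread = abs(.data$icer_at_high - .data$icer_at_low)) |>
    arrange(desc(.data$spread))
  structure(out, class = c("psm_tornado", class(out)),
            icer_base = base_ce$icer, wtp = config$settings$wtp)
}

# method-of-moments beta/gamma parameterisation treating (low, high) as a
# 95% interval, so sd = (high - low) / 3.92
draw_param <- function(n, base, low, high, dist) {
  s <- (high - low) / 3.92
  if (s <= 0 || dist == "fixed") return(rep(base, n))
  switch(dist,
    beta = {
      v <- s^2
      vmax <- base * (1 - base)
      if (v >= vmax) {
        warn(sprintf("beta moments infeasible (sd %.3g too large for mean %.3g); variance scaled down",
                     s, base))
        v <- 0.9 * vmax
      }
      k <- base * (1 - base) / v - 1
      rbeta(n, base * k, (1 - base) * k)
    },
    gamma = {
      shape <- base^2 / s^2
      rgamma(n, shape = shape, rate = shape / base)
    },
    lognormal = {
      sdlog <- (log(high) - log(low)) / 3.92
      rlnorm(n, log(base), sdlog)
    },
    abort(sprintf("unknown PSA distribution '%s'", dist),
          class = "psmcea_invalid_parameter"))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter vectors (beta utilities, gamma costs, lognormal
#' hazard ratios; discount rate and start age held fixed), reruns the full
#' deterministic model per draw, and records the incremental outcomes.
#'
#' @param config A [ce_config()].
#' @param space A [param_space()] tibble.
#' @param n Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; the analysis is reproducible for a fixed
#'   seed.
#' @return A `psm_psa`: list with `samples` (one row per draw:
#'   parameters, `delta_cost`, `delta_qaly`, `icer`, `nmb` at the
#'   configured WTP), `wtp`, and the base-case `psm_ce`.
#' @export
psa <- function(config, space = param_space(config), n = 1000, seed = 1) {
  if (n < 1) abort("n must be >= 1", class = "psmcea_invalid_parameter")
  sampled <- filter(space, .data$dist != "fixed")
  draws <- withr_seed(seed, {
    out <- map2(split(sampled, seq_len(nrow(sampled))), seq_len(nrow(sampled)),
                function(row, i) draw_param(n, row$base, row$low, row$high, row$dist))
    setNames(out, sampled$param)
  })
  draws <- as_tibble(draws)
  wtp <- config$settings$wtp
  res <- map(seq_len(n), function(i) {
    ce <- run_model(config, as.list(draws[i, ]))
    tibble(delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
           icer = ce$icer)
  })
  samples <- bind_cols(draws, bind_rows(res)) |>
    mutate(nmb = wtp * .data$delta_qaly - .data$delta_cost)
  structure(list(samples = samples, wtp = wtp, base = run_base_case(config),
                 n = n, seed = seed),
            class = "psm_psa")
}

#' @export
print.psm_psa <- function(x, ...) {
  p_ce <- mean(x$samples$nmb >= 0)
  cat(sprintf("<psm_psa> %d draws | P(cost-effective at WTP $%.2f) = %.1f%%\n",
              x$n, x$wtp, 100 * p_ce))
  cat(sprintf("  mean delta cost $%.0f, mean delta QALY %.3f\n",
              mean(x$samples$delta_cost), mean(x$samples$delta_qaly)))
  invisible(x)
}

#' @export
tidy.psm_psa <- function(x, ...) x$samples

#' @export
glance.psm_psa <- function(x, ...) {
  tibble(n = x$n, wtp = x$wtp,
         p_cost_effective = mean(x$samples$nmb >= 0),
         mean_delta_cost = mean(x$samples$delta_cost),
         mean_delta_qaly = mean(x$samples$delta_qaly))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' non-negative net monetary benefit `wtp * dQALY - dCost`.
#'
#' @param x A `psm_psa` or its `samples` tibble.
#' @param wtp_grid WTP grid in $/QALY (default $0-$340,000 by $2,500).
#' @return Tibble `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(x, wtp_grid = seq(0, 340000, by = 2500)) {
  samples <- if (inherits(x, "psm_psa")) x$samples else x
  if (nrow(samples) == 0) abort("no PSA samples", class = "psmcea_empty_input")
  prob <- vapply(wtp_grid, function(w) {
    mean(w * samples$delta_qaly - samples$delta_cost >= 0)
  }, numeric(1))
  structure(tibble(wtp = wtp_grid, prob_cost_effective = prob),
            class = c("psm_ceac", class(tibble())))
}

#' Threshold analysis on the pembrolizumab cycle price
#'
#' The ICER is affine in the pembrolizumab cost per cycle (the price
#' enters incremental cost linearly and leaves effects untouched), so the
#' break-even price solves a linear equation from two model evaluations; a
#' confirmation run verifies the solution.
#'
#' @param config A [ce_config()].
#' @param wtp Willingness-to-pay threshold (default from settings).
#' @return Tibble `threshold_cycle_cost`, `pct_reduction`,
#'   `icer_at_threshold`, `feasible`.
#' @export
threshold_price <- function(config, wtp = config$settings$wtp) {
  p0 <- config$costs$base[match("pembrolizumab", config$costs$item)]
  ce0 <- run_base_case(config)
  if (ce0$status == "icer" && ce0$icer <= wtp) {
    return(tibble(threshold_cycle_cost = p0, pct_reduction = 0,
                  icer_at_threshold = ce0$icer, feasible = TRUE))
  }
  ce_zero <- run_model(config, list(cost_pembrolizumab = 0))
  if (!(ce_zero$status %in% c("icer", "dominant")) ||
      (ce_zero$status == "icer" && ce_zero$icer > wtp)) {
    return(tibble(threshold_cycle_cost = NA_real_, pct_reduction = NA_real_,
                  icer_at_threshold = NA_real_, feasible = FALSE))
  }
  # ICER(p) = a + b p from two evaluations; ce_zero gives the intercept on
  # the incremental-cost scale
  slope <- (ce0$icer - if (ce_zero$status == "icer") ce_zero$icer else
              ce_zero$delta_cost / ce_zero$delta_qaly) / p0
  intercept <- ce0$icer - slope * p0
  p_star <- (wtp - intercept) / slope
  confirm <- run_model(config, list(cost_pembrolizumab = p_star))
  tibble(threshold_cycle_cost = p_star,
         pct_reduction = 100 * (1 - p_star / p0),
         icer_at_threshold = confirm$icer, feasible = TRUE)
}

#' Subgroup analysis: rerun with subgroup hazard ratios
#'
#' @param config A [ce_config()].
#' @param hr_os,hr_pfs Subgroup hazard ratios (> 0).
#' @param label Subgroup name for the output.
#' @return A `psm_ce` with attribute `subgroup`.
#' @export
subgroup_run <- function(config, hr_os, hr_pfs, label = "subgroup") {
  stop_if_not_scalar_pos(hr_os, "hr_os")
  stop_if_not_scalar_pos(hr_pfs, "hr_pfs")
  ce <- run_model(config, list(hr_os = hr_os, hr_pfs = hr_pfs))
  attr(ce, "subgroup") <- label
  ce
}

#' Default biomarker / histology subgroups
#'
#' @return Tibble `subgroup`, `hr_os`, `hr_pfs`: squamous-cell carcinoma
#'   (0.72, 0.65) and PD-L1 CPS >= 10 (0.62, 0.51).
#' @export
default_subgroups <- function() {
  tibble::tribble(
    ~subgroup,                             ~hr_os, ~hr_pfs,
    "oesophageal squamous cell carcinoma", 0.72,   0.65,
    "PD-L1 CPS >= 10",                     0.62,   0.51
  )
}
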