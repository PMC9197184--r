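#' Default pipeline configuration
#'
#' Nested list covering every stage of the analysis pipeline: the
#' synthetic-trial generation block (used when no digitized-curve files
#' are given), parameter blocks with low/base/high bounds, model settings
#' and analysis switches. [load_config()] merges a user file over these
#' defaults, so an empty file yields a pure synthetic run.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    synthetic = list(
      n_per_arm = 374, os_median = 9.8, pfs_median = 5.8,
      os_shape = 1.5, pfs_shape = 1.6,
      hr_os = 0.73, hr_pfs = 0.65,
      dropout_rate = 0.01, admin_cutoff = 22.6
    ),
    files = list(curve_dir = NULL, life_table = NULL),
    hr = list(os = list(base = 0.73, low = 0.58, high = 0.88),
              pfs = list(base = 0.65, low = 0.52, high = 0.78)),
    settings = list(cycle_days = 21, discount_annual = 0.03, start_age = 63,
                    horizon_years = 30, wtp = 31304.31),
    regimen = list(uptake_trt = 0.43, uptake_ctrl = 0.47,
                   pembro_cap = 35, chemo_cap = 6),
    analyses = list(oneway = TRUE, psa = TRUE, ceac = TRUE,
                    threshold = TRUE, subgroups = TRUE, n_psa = 1000),
    fit = list(direct_trt_fit = FALSE, total_events = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next # YAML/JSON writers drop or null out empties
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration file
#'
#' YAML or JSON; unknown top-level keys are rejected, bounds are checked
#' (`low <= base <= high`), and missing entries fall back to
#' [default_config()]. An empty file returns the defaults (a pure
#' synthetic run).
#'
#' @param path File path, or `NULL` for defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' not found", path),
                                  class = "psmcea_invalid_input")
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
              class = "psmcea_invalid_input")
      }
      cfg <- merge_config(cfg, user)
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (ep in names(cfg$hr)) {
    b <- cfg$hr[[ep]]
    if (!(b$low <= b$base && b$base <= b$high)) {
      abort(sprintf("hr.%s: bounds must satisfy low <= base <= high", ep),
            class = "psmcea_invalid_input")
    }
    if (b$low <= 0) abort(sprintf("hr.%s.low must be > 0", ep),
                          class = "psmcea_invalid_input")
  }
  with(cfg$settings, {
    if (discount_annual < 0 || discount_annual > 0.10)
      abort("settings.discount_annual out of range", class = "psmcea_invalid_input")
  })
  for (f in c("uptake_trt", "uptake_ctrl")) {
    if (cfg$regimen[[f]] < 0 || cfg$regimen[[f]] > 1) {
      abort(sprintf("regimen.%s must be in [0, 1]", f), class = "psmcea_invalid_input")
    }
  }
  cfg
}

config_settings <- function(cfg) {
  do.call(model_settings, cfg$settings)
}

#' Run the full analysis pipeline
#'
#' End-to-end wiring: generate (or load) digitized-curve fixtures,
#' reconstruct pseudo-IPD per arm and endpoint, fit the five parametric
#' families to the control arm and select by AIC, then run the base case
#' and every enabled sensitivity analysis. All CSV outputs plus a manifest
#' JSON (seed, package version, assumption flags) are written to
#' `out_dir` when given.
#'
#' @param config A configuration list from [load_config()] /
#'   [default_config()].
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `psm_pipeline` list: `fits`, `best`, `config_used`,
#'   `base_case`, `tornado`, `psa`, `ceac`, `threshold`, `subgroups`,
#'   `reconstruction_error`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL) {
  config <- validate_config(config)
  seed <- as.integer(seed)
  sy <- config$synthetic

  # stage 1: fixtures (synthetic trial emulating the digitization product)
  trial <- synth_trial(n_per_arm = sy$n_per_arm,
                       os_median = sy$os_median, pfs_median = sy$pfs_median,
                       os_shape = sy$os_shape, pfs_shape = sy$pfs_shape,
                       hr_os = sy$hr_os, hr_pfs = sy$hr_pfs,
                       censor = censor_spec(sy$admin_cutoff, sy$dropout_rate),
                       seed = seed)
  life_table <- if (!is.null(config$files$life_table)) {
    check_life_table(as_tibble(utils::read.csv(config$files$life_table)))
  } else {
    trial$life_table
  }

  # stage 2: pseudo-IPD reconstruction from the digitized artifacts
  recon <- map(trial$artifacts, ~ reconstruct_ipd(.x$curve, .x$risk,
                                                  total_events = config$fit$total_events))
  recon_err <- map_dbl(names(recon), function(nm) {
    grid <- trial$artifacts[[nm]]$curve$time_months
    max(abs(km_step_fun(km_estimate(recon[[nm]]))(grid) -
              trial$artifacts[[nm]]$curve$survival))
  })
  names(recon_err) <- names(recon)

  # stage 3: parametric fits, AIC selection (control arm drives the model)
  fits <- list(os = fit_all_families(recon$ctrl_os),
               pfs = fit_all_families(recon$ctrl_pfs))
  best <- list(os = select_best(fits$os), pfs = select_best(fits$pfs))
  trt_fits <- if (isTRUE(config$fit$direct_trt_fit)) {
    list(os = select_best(fit_all_families(recon$trt_os)),
         pfs = select_best(fit_all_families(recon$trt_pfs)))
  } else {
    list(os = NULL, pfs = NULL)
  }

  cfg <- ce_config(best$os, best$pfs,
                   hr_os = config$hr$os$base, hr_pfs = config$hr$pfs$base,
                   life_table = life_table, settings = config_settings(config),
                   uptake_trt = config$regimen$uptake_trt,
                   uptake_ctrl = config$regimen$uptake_ctrl,
                   pembro_cap = config$regimen$pembro_cap,
                   chemo_cap = config$regimen$chemo_cap,
                   trt_os_fit = trt_fits$os, trt_pfs_fit = trt_fits$pfs)
  space <- param_space(cfg)
  i <- match(c("hr_os", "hr_pfs"), space$param)
  space$low[i] <- c(config$hr$os$low, config$hr$pfs$low)
  space$high[i] <- c(config$hr$os$high, config$hr$pfs$high)

  # stage 4: analyses
  base_case <- run_base_case(cfg)
  tornado <- if (isTRUE(config$analyses$oneway)) one_way(cfg, space)
  psa_res <- if (isTRUE(config$analyses$psa)) {
    psa(cfg, space, n = config$analyses$n_psa, seed = seed + 1000L)
  }
  ceac_res <- if (isTRUE(config$analyses$ceac) && !is.null(psa_res)) ceac(psa_res)
  thr <- if (isTRUE(config$analyses$threshold)) threshold_price(cfg)
  subs <- if (isTRUE(config$analyses$subgroups)) {
    sg <- default_subgroups()
    bind_rows(pmap(sg, function(subgroup, hr_os, hr_pfs) {
      ce <- subgroup_run(cfg, hr_os, hr_pfs, subgroup)
      tibble(subgroup = subgroup, hr_os = hr_os, hr_pfs = hr_pfs,
             delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
             icer = ce$icer)
    }))
  }

  out <- structure(list(
    trial = trial, reconstruction = recon, reconstruction_error = recon_err,
    fits = fits, best = best, config_used = config, ce_config = cfg,
    base_case = base_case, tornado = tornado, psa = psa_res,
    ceac = ceac_res, threshold = thr, subgroups = subs, seed = seed
  ), class = "psm_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.psm_pipeline <- function(x, ...) {
  cat("<psm_pipeline>\n")
  cat(sprintf("  best fits: OS %s (AIC %.1f), PFS %s (AIC %.1f)\n",
              x$best$os$family, x$best$os$aic, x$best$pfs$family, x$best$pfs$aic))
  cat(sprintf("  max reconstruction sup-norm error: %.4f\n",
              max(x$reconstruction_error)))
  print(x$base_case)
  invisible(x)
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                              row.names = FALSE)
  bc <- glance(x$base_case)
  wcsv(bind_cols(tidy(x$base_case) |>
                   tidyr::pivot_wider(names_from = "strategy",
                                      values_from = c("cost", "ly", "qaly")),
                 bc), "base_case.csv")
  if (!is.null(x$tornado)) wcsv(as_tibble(x$tornado), "tornado.csv")
  if (!is.null(x$psa)) wcsv(x$psa$samples, "psa_samples.csv")
  if (!is.null(x$ceac)) wcsv(x$ceac, "ceac.csv")
  if (!is.null(x$threshold)) {
    jsonlite::write_json(as.list(x$threshold), file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(x$subgroups)) wcsv(x$subgroups, "subgroups.csv")
  manifest <- list(
    seed = x$seed,
    package = "psmcea",
    version = as.character(utils::packageVersion("psmcea")),
    best_fit = list(os = x$best$os$family, pfs = x$best$pfs$family),
    reconstruction_error = as.list(x$reconstruction_error),
    assumptions = list(
      start_age = x$ce_config$settings$start_age,
      horizon_years = x$ce_config$settings$horizon_years,
      ae_incidences = "synthetic defaults (not trial-reported)",
      hr_psa_distribution = "lognormal from 95% CI",
      second_line_duration = "uncapped while in progressed disease"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Write the synthetic fixture CSVs for external use
#'
#' Emits the CSV schemas consumed by the pipeline: per arm/endpoint
#' digitized curve (`time_months`, `survival`), risk table
#' (`time_months`, `n_at_risk`), pseudo-IPD (`time_months`, `event`) and
#' the life table (`age`, `q_annual`).
#'
#' @param trial A [synth_trial()] result.
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_trial_fixtures <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(trial$artifacts)) {
    f1 <- file.path(dir, paste0(nm, "_curve.csv"))
    f2 <- file.path(dir, paste0(nm, "_risk.csv"))
    f3 <- file.path(dir, paste0(nm, "_ipd.csv"))
    utils::write.csv(trial$artifacts[[nm]]$curve, f1, row.names = FALSE)
    utils::write.csv(trial$artifacts[[nm]]$risk, f2, row.names = FALSE)
    utils::write.csv(trial$ipd[[nm]], f3, row.names = FALSE)
    files <- c(files, f1, f2, f3)
  }
  f4 <- file.path(dir, "life_table.csv")
  utils::write.csv(trial$life_table, f4, row.names = FALSE)
  invisible(c(files, f4))
}
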