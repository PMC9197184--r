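# Session-cached fixtures: heavier objects are built once and shared across
# test files (testthat runs all files in one session).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

ctrl_os_spec <- function() calibrate_loglogistic(9.8, 1.5)
ctrl_pfs_spec <- function() calibrate_loglogistic(5.8, 1.6)

# cheap deterministic config: calibrated specs stand in for fitted curves
spec_config <- function(...) {
  ce_config(ctrl_os_spec(), ctrl_pfs_spec(), ...)
}

# default synthetic trial (n = 374/arm), shared
default_trial <- function() fixture("trial", synth_trial(seed = 2020))

# full default pipeline run (fits + all analyses incl. 1000-draw PSA)
default_pipeline <- function() {
  fixture("pipeline", run_pipeline(default_config(), seed = 101))
}

# build a psm_trace by hand from occupancy rows (for toy-ledger tests)
manual_trace <- function(pfs, pd, settings = model_settings()) {
  n <- length(pfs)
  cyc <- 0:(n - 1)
  t_years <- cyc * settings$cycle_days / 365.25
  out <- tibble::tibble(cycle = cyc, time_years = t_years,
                        age = settings$start_age + t_years,
                        pfs = pfs, pd = pd, dead = 1 - pfs - pd)
  structure(out, class = c("psm_trace", class(out)), settings = settings)
}
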