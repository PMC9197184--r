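test_that("the cohort starts progression-free and states partition to one", {
  tr <- build_trace(ctrl_os_spec(), ctrl_pfs_spec(), make_life_table())
  expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
               c(pfs = 1, pd = 0, dead = 0))
  expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
  expect_true(all(tr$pfs >= 0 & tr$pfs <= 1))
  expect_true(all(diff(tr$dead) >= -1e-12))
  expect_true(all(diff(tr$pfs) <= 1e-12))
})

test_that("identical OS and PFS curves leave no one in progressed disease", {
  sp <- ctrl_os_spec()
  tr <- build_trace(sp, sp, make_life_table())
  expect_true(all(tr$pd < 1e-12))
})

test_that("background mortality floor compounds the life-table hazard exactly", {
  lt <- tibble::tibble(age = 0:120, q_annual = c(rep(0.5, 120), 1))
  st <- model_settings(start_age = 40, horizon_years = 5)
  tr <- build_trace(function(t) rep(1, length(t)), function(t) rep(1, length(t)),
                    lt, st)
  expected <- 1 - 0.5^(tr$cycle * 21 / 365.25)
  expect_equal(tr$dead, expected, tolerance = 1e-9)
})

test_that("death never falls below what the life table alone implies", {
  st <- model_settings()
  lt <- make_life_table()
  tr <- build_trace(ctrl_os_spec(), ctrl_pfs_spec(), lt, st)
  bg <- build_trace(function(t) rep(1, length(t)), function(t) rep(1, length(t)),
                    lt, st)
  n <- min(nrow(tr), nrow(bg))
  expect_true(all(tr$dead[1:n] >= bg$dead[1:n] - 1e-12))
})

test_that("ages outside the life table are an error", {
  lt <- make_life_table(max_age = 70)
  expect_error(build_trace(ctrl_os_spec(), ctrl_pfs_spec(), lt,
                           model_settings(start_age = 63, horizon_years = 30)),
               class = "psmcea_invalid_input")
})

test_that("half-cycle correction is the trapezoid rule", {
  expect_equal(half_cycle_correct(rep(3, 7)), rep(3, 6))
  expect_equal(half_cycle_correct(c(1, 0)), 0.5)
  lin <- seq(1, 0, by = -0.1)
  # trapezoid integral of a linear series is exact
  expect_equal(sum(half_cycle_correct(lin)),
               (lin[1] + lin[11]) / 2 + sum(lin[2:10]))
  expect_error(half_cycle_correct(1), class = "psmcea_invalid_input")
})

test_that("discounting follows (1+r)^(-t) on the cycle clock", {
  st <- model_settings()
  expect_equal(discount_factor(0, st), 1)
  st0 <- model_settings(discount_annual = 0)
  expect_equal(discount_factor(0:100, st0), rep(1, 101))
  cycles_per_year <- 365.25 / 21
  expect_equal(discount_factor(cycles_per_year, st), 1 / 1.03, tolerance = 1e-12)
})

test_that("life years reproduce closed-form cases", {
  st <- model_settings(discount_annual = 0)
  # instant death after one cycle: half a cycle of life
  tr1 <- manual_trace(pfs = c(1, 0), pd = c(0, 0), settings = st)
  expect_equal(life_years(tr1), 0.5 * 21 / 365.25)
  # immortal cohort over the horizon: LY equals the horizon length
  lt0 <- tibble::tibble(age = 0:120, q_annual = c(rep(0, 120), 1))
  tr2 <- build_trace(function(t) rep(1, length(t)), function(t) rep(1, length(t)),
                     lt0, model_settings(discount_annual = 0, horizon_years = 10,
                                         start_age = 40))
  expect_equal(life_years(tr2), floor(10 * 365.25 / 21) * 21 / 365.25,
               tolerance = 1e-9)
  # exponential survival: mean life = 1/lambda
  lam <- 1 / 10 # per month
  tr3 <- build_trace(function(t) exp(-lam * t), function(t) exp(-lam * t),
                     lt0, model_settings(discount_annual = 0, horizon_years = 30,
                                         start_age = 40))
  ly_months <- life_years(tr3) * 12
  expect_lt(abs(ly_months - 1 / lam) / (1 / lam), 0.005)
})

test_that("discount zero and unit utilities make QALYs equal LYs", {
  st <- model_settings(discount_annual = 0)
  tr <- build_trace(ctrl_os_spec(), ctrl_pfs_spec(), make_life_table(), st)
  u1 <- tibble::tibble(state = c("pfs", "pd"), base = c(1, 1),
                       low = c(1, 1), high = c(1, 1))
  res <- accrue(tr, default_regimens()$ctrl, utilities = u1, settings = st,
                arm = "ctrl")
  expect_equal(res$qaly, res$ly, tolerance = 1e-12)
  expect_equal(res$ly, life_years(tr, st), tolerance = 1e-12)
})
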