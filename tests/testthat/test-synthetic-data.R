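test_that("log-logistic calibration puts the median where asked", {
  for (m in c(9.8, 5.8, 12.4)) {
    sp <- calibrate_loglogistic(m, 1.5)
    expect_equal(sp$params[["scale"]], m)
    expect_equal(dist_survival(sp, m), 0.5)
  }
  expect_error(calibrate_loglogistic(-1, 1.5), class = "psmcea_invalid_parameter")
  expect_error(calibrate_loglogistic(9.8, 0), class = "psmcea_invalid_parameter")
})

test_that("log-logistic tail matches closed form and the hazard-integral oracle", {
  sp <- calibrate_loglogistic(9.8, 1.5)
  expect_equal(dist_survival(sp, 19.6), 1 / (1 + 2^1.5), tolerance = 1e-12)
  # independent oracle: S(t) = exp(-integral of hazard)
  H <- integrate(function(u) dist_hazard(sp, u), 0, 19.6, rel.tol = 1e-10)$value
  expect_equal(dist_survival(sp, 19.6), exp(-H), tolerance = 1e-7)
})

test_that("simulation censoring machinery behaves at its edges", {
  sp <- ctrl_os_spec()
  none <- simulate_ipd(sp, censor_spec(Inf, 0), n = 200, seed = 5)
  expect_true(all(none$event == 1))
  cut <- simulate_ipd(dist_spec("loglogistic", scale = 1e6, shape = 1.5),
                      censor_spec(admin_cutoff = 0.01, dropout_rate = 0),
                      n = 200, seed = 5)
  expect_true(mean(cut$event) < 0.05)
  expect_true(all(cut$time_months <= 0.01))
})

test_that("simulated exponential times have the analytic mean", {
  lam <- 0.2
  ipd <- simulate_ipd(dist_spec("exponential", rate = lam),
                      censor_spec(Inf, 0), n = 10000, seed = 11)
  se <- (1 / lam) / sqrt(10000)
  expect_lt(abs(mean(ipd$time_months) - 1 / lam), 3 * se)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  a <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 50, seed = 99)
  b <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 50, seed = 99)
  expect_identical(a, b)
  c <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 50, seed = 100)
  expect_false(identical(a, c))
})

test_that("empirical survival at the true median approaches one half", {
  sp <- ctrl_os_spec()
  ipd <- simulate_ipd(sp, censor_spec(Inf, 0), n = 50000, seed = 21)
  expect_lt(abs(mean(ipd$time_months > 9.8) - 0.5), 0.01)
})

test_that("hazard-ratio sampling produces the power-transformed survival curve", {
  sp <- ctrl_os_spec()
  ipd <- simulate_ipd(sp, censor_spec(Inf, 0), n = 50000, seed = 22, hr = 0.73)
  # S_trt(9.8) should be 0.5^0.73
  expect_lt(abs(mean(ipd$time_months > 9.8) - 0.5^0.73), 0.01)
})

test_that("KM artifacts reproduce hand product-limit values", {
  one <- tibble::tibble(time_months = 2, event = 1)
  art <- make_km_artifacts(one, grid_step = 1, risk_interval = 1)
  expect_equal(art$curve$survival[art$curve$time_months < 2], c(1, 1))
  expect_equal(art$curve$survival[art$curve$time_months >= 2], 0)
  four <- tibble::tibble(time_months = 1:4, event = c(1, 0, 1, 0))
  art4 <- make_km_artifacts(four, grid_step = 1, risk_interval = 1)
  sf <- art4$curve$survival[match(c(1, 3), art4$curve$time_months)]
  expect_equal(sf, c(0.75, 0.375))
  expect_equal(art4$risk$n_at_risk[art4$risk$time_months == 0], 4L)
  expect_error(make_km_artifacts(four[0, ]), class = "psmcea_empty_input")
})

test_that("KM curves are valid survival step functions", {
  ipd <- simulate_ipd(ctrl_os_spec(), censor_spec(), n = 150, seed = 3)
  art <- make_km_artifacts(ipd)
  s <- art$curve$survival
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s[1], 1)
  expect_true(all(diff(art$risk$n_at_risk) <= 0))
})

test_that("Gompertz-Makeham life table evaluates, is monotone, ends at q = 1", {
  lt0 <- make_life_table(a = 0, b = 1e-15, c = 1.0001, max_age = 50)
  expect_true(all(lt0$q_annual[-nrow(lt0)] < 1e-10))
  lt <- make_life_table(a = 0.001, b = 5e-5, c = 1.09, max_age = 100)
  expect_true(all(diff(lt$q_annual) >= 0))
  expect_equal(lt$q_annual[nrow(lt)], 1)
  # direct evaluation at age 63 against independent arithmetic
  expect_equal(lt$q_annual[lt$age == 63],
               1 - exp(-(0.001 + 5e-5 * 1.09^63)), tolerance = 1e-12)
})

test_that("the synthetic trial bundle is complete and internally consistent", {
  trial <- default_trial()
  expect_named(trial$ipd, c("ctrl_os", "ctrl_pfs", "trt_os", "trt_pfs"))
  expect_true(all(vapply(trial$ipd, nrow, integer(1)) == 374L))
  # treatment arms should survive longer than control (HR < 1)
  km_t <- mean(trial$ipd$trt_os$time_months)
  km_c <- mean(trial$ipd$ctrl_os$time_months)
  expect_gt(km_t, km_c)
})
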