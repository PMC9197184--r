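test_that("equal arms with equal costs produce a null comparison", {
  cfg <- spec_config(hr_os = 1, hr_pfs = 1)
  # strip the arm-specific costs: no pembrolizumab, same uptake, same AEs
  cfg$costs$base[cfg$costs$item == "pembrolizumab"] <- 0
  cfg$uptake_trt <- cfg$uptake_ctrl <- 0.45
  cfg$ae$incidence_trt <- cfg$ae$incidence_ctrl
  ce <- run_base_case(cfg)
  expect_lt(abs(ce$delta_qaly), 1e-12)
  expect_lt(abs(ce$delta_cost), 1e-8)
})

test_that("raising only the pembrolizumab price strictly raises the ICER", {
  cfg <- spec_config()
  i1 <- run_base_case(cfg)$icer
  i2 <- run_model(cfg, list(cost_pembrolizumab = 2 * 5625.75))$icer
  expect_gt(i2, i1)
})

test_that("one-way analysis orders by spread and honours degenerate bounds", {
  cfg <- spec_config()
  space <- param_space(cfg)
  # collapse one parameter's bounds onto base: spread must be zero
  i <- which(space$param == "cost_cisplatin")
  space$low[i] <- space$high[i] <- space$base[i]
  tw <- one_way(cfg, space)
  expect_true(all(diff(tw$spread) <= 1e-9))
  expect_equal(tw$spread[tw$parameter == "cost_cisplatin"], 0)
  # worse PFS effect (higher HR) cannot make the intervention look better
  base_icer <- attr(tw, "icer_base")
  expect_gt(tw$icer_at_high[tw$parameter == "hr_pfs"], base_icer)
  expect_error(one_way(cfg, tibble::tibble(param = "bogus", base = 1, low = 1,
                                           high = 1, dist = "fixed", role = "x")),
               class = "psmcea_invalid_parameter")
})

test_that("lower hazard ratios never increase the ICER", {
  cfg <- spec_config()
  base <- run_base_case(cfg)$icer
  better <- run_model(cfg, list(hr_os = 0.62, hr_pfs = 0.51))$icer
  expect_lte(better, base)
})

test_that("PSA is seed-reproducible and collapses under zero variance", {
  cfg <- spec_config()
  s1 <- psa(cfg, n = 25, seed = 5)
  s2 <- psa(cfg, n = 25, seed = 5)
  expect_identical(s1$samples, s2$samples)
  space0 <- param_space(cfg)
  space0$low <- space0$high <- space0$base
  s0 <- psa(cfg, space0, n = 10, seed = 5)
  base <- run_base_case(cfg)
  expect_true(all(abs(s0$samples$icer - base$icer) < 1e-9))
})

test_that("PSA draws respect their distribution supports and moments", {
  cfg <- spec_config()
  s <- psa(cfg, n = 400, seed = 9)
  expect_true(all(s$samples$u_pfs >= 0 & s$samples$u_pfs <= 1))
  expect_true(all(s$samples$u_pd >= 0 & s$samples$u_pd <= 1))
  expect_true(all(s$samples$cost_pembrolizumab > 0))
  # lognormal HR_OS: mean within 3 SE of 0.73 (mean of LN slightly above median)
  sdlog <- (log(0.88) - log(0.58)) / 3.92
  ln_mean <- 0.73 * exp(sdlog^2 / 2)
  ln_sd <- ln_mean * sqrt(exp(sdlog^2) - 1)
  expect_lt(abs(mean(s$samples$hr_os) - ln_mean), 3 * ln_sd / sqrt(400))
})

test_that("the acceptability curve is a nondecreasing probability in WTP", {
  cfg <- spec_config()
  s <- fixture("psa_spec_200", psa(cfg, n = 200, seed = 13))
  cc <- ceac(s, wtp_grid = seq(0, 340000, by = 10000))
  expect_true(!is.unsorted(cc$prob_cost_effective))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  # with all delta costs positive, paying nothing is never cost-effective
  expect_true(all(s$samples$delta_cost > 0))
  expect_equal(cc$prob_cost_effective[cc$wtp == 0], 0)
  # far beyond every drawn ICER the probability reaches 1
  cc_hi <- ceac(s, wtp_grid = max(s$samples$icer) * 1.01)
  expect_equal(cc_hi$prob_cost_effective, 1)
})

test_that("threshold price analysis is self-consistent and handles edges", {
  cfg <- spec_config()
  thr <- threshold_price(cfg)
  expect_true(thr$feasible)
  expect_lt(abs(thr$icer_at_threshold - cfg$settings$wtp) / cfg$settings$wtp, 1e-4)
  expect_true(thr$pct_reduction > 0 && thr$pct_reduction < 100)
  # WTP at the base ICER: no reduction needed
  base <- run_base_case(cfg)
  thr0 <- threshold_price(cfg, wtp = base$icer * 1.0001)
  expect_equal(thr0$pct_reduction, 0)
  # WTP below the ICER at price zero: infeasible
  zero_icer <- run_model(cfg, list(cost_pembrolizumab = 0))$icer
  thr_inf <- threshold_price(cfg, wtp = zero_icer * 0.5)
  expect_false(thr_inf$feasible)
})

test_that("subgroup reruns reduce to the base case at the overall HRs", {
  cfg <- spec_config()
  base <- run_base_case(cfg)
  same <- subgroup_run(cfg, cfg$hr_os, cfg$hr_pfs, "all-comers")
  expect_equal(same$icer, base$icer, tolerance = 1e-12)
  null <- subgroup_run(cfg, 1, 1)
  expect_equal(null$status, "non-comparable")
})
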