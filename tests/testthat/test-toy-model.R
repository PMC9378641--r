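test_that("analytic steady state equals input times turnover per pool", {
  p <- toy_params(npp0 = 10, tau_v_nat = 20, has_litter = FALSE)
  ss <- analytic_steady_state(p, f_ag0 = 0)
  expect_equal(ss[["Cv"]], 200)

  p2 <- toy_params(npp0 = 10, tau_s0 = 25, has_litter = FALSE)
  expect_equal(analytic_steady_state(p2, 0)[["Cs"]], 250)

  # litter+soil: frozen against the 2x2 linear balance solved by hand:
  # Clit/tau_lit = NPP  and  Cs/tau_s = eps * Clit/tau_lit
  p3 <- toy_params(npp0 = 10, eps_lit = 0.5, tau_lit = 3, tau_s0 = 25)
  ss3 <- analytic_steady_state(p3, 0)
  expect_equal(ss3[["Clit"]], 30)
  expect_equal(ss3[["Cs"]], 125)

  expect_error(toy_params(tau_s0 = 0), "turnover")
})

test_that("one step follows the explicit annual balance", {
  p <- toy_params(npp0 = 10, tau_v_nat = 20, has_litter = FALSE,
                  beta = 0.1, co2_ref = 284)
  ss <- analytic_steady_state(p, 0)
  base <- list(co2 = 284, t_anom = 0, f_ag = 0, d_f_ag = 0)
  stp <- step_toy_model(ss, p, base)
  expect_equal(stp$state, ss)           # steady state is a fixed point
  expect_equal(stp$fluxes$NBP, 0)

  # NPP=11 via CO2 increase: dCv = 11 - 200/20 = 1
  co2_up <- 284 * exp(1)                # solves 1 + beta ln(c/cref) = 1.1
  stp2 <- step_toy_model(ss, p, list(co2 = co2_up, t_anom = 0,
                                     f_ag = 0, d_f_ag = 0))
  expect_equal(stp2$fluxes$NPP, 11)
  expect_equal(stp2$state[["Cv"]], 201)

  # clearing flux: E_lu = 1 * 0.01 * 200 = 2, half emitted, half to soil
  p3 <- toy_params(npp0 = 10, tau_v_nat = 20, has_litter = FALSE,
                   lambda_lu = 1, p_atm = 0.5)
  stp3 <- step_toy_model(analytic_steady_state(p3, 0), p3,
                         list(co2 = 284, t_anom = 0, f_ag = 0.01,
                              d_f_ag = 0.01))
  expect_equal(stp3$fluxes$E_lu, 2)
  tau_eff <- 0.99 * 20 + 0.01 * p3$tau_v_ag
  expect_equal(stp3$fluxes$f_vs - 200 / tau_eff, 1)
  expect_equal(stp3$fluxes$NBP,
               stp3$fluxes$NPP - stp3$fluxes$Rh - 0.5 * 2)

  # massive one-year clearing drives vegetation negative
  expect_error(step_toy_model(c(Cv = 200, Clit = 0, Cs = 250), p3,
                              list(co2 = 284, t_anom = 0, f_ag = 0.9,
                                   d_f_ag = 0.9)),
               "negative")
})

test_that("mass balance NBP = sum of pool changes holds every year", {
  frc <- default_forcing(seed = 11)
  for (flags in list(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
                     c(TRUE, TRUE, TRUE))) {
    p <- toy_params(has_litter = flags[1], has_cwd = flags[2],
                    litter_in_soil = flags[3], gamma = 0.01)
    run <- run_scenario(p, frc, "S3")
    tot <- run$series$cVeg + aggregate_soil_pools(run)
    resid <- run$series$NBP[-nrow(run$series)] - diff(tot)
    expect_lt(max(abs(resid)) / max(abs(run$series$NBP)), 1e-10)
  }
})

test_that("control runs preserve the analytic steady state", {
  frc <- quiet_forcing()
  p <- toy_params(q10 = 2, beta = 0.5, gamma = 0.01)
  run <- run_scenario(p, frc, "S0", window = c(1860, 2020))  # 161 years
  for (v in c("cVeg", "cSoil", "cLitter")) {
    x <- run$series[[v]]
    expect_lt(max(abs(x - x[1])) / x[1], 1e-9)
  }
  expect_lt(max(abs(run$series$NBP)), 1e-9)
})

test_that("factorial scenarios nest when a forcing axis is flat", {
  # flat CO2: S1 = S0
  frc_flat_co2 <- generate_forcing(1850:2020,
                                   co2_spec = list(co2_ref = 284,
                                                   growth_rate = 0),
                                   seed = 1)
  p <- toy_params(gamma = 0.01)
  expect_equal(run_scenario(p, frc_flat_co2, "S1")$series,
               run_scenario(p, frc_flat_co2, "S0")$series)
  # flat land use: S3 = S2
  frc_flat_lu <- quiet_forcing(sigma = 0.1)
  expect_equal(run_scenario(p, frc_flat_lu, "S3")$series,
               run_scenario(p, frc_flat_lu, "S2")$series)
  # S1 grows vegetation under fertilization
  s1 <- run_scenario(p, default_forcing(), "S1")$series
  expect_gt(s1$cVeg[nrow(s1)], s1$cVeg[1])
})

test_that("rising inputs lower aggregate soil turnover at constant rates", {
  # false-priming: litter+soil with fixed pool-level turnover (q10 = 1),
  # rising CO2 shifts mass toward the fast litter pool and shortens the
  # diagnosed aggregate turnover (Clit+Cs)/Rh
  p <- toy_params(q10 = 1, gamma = 0, has_litter = TRUE,
                  eps_lit = 0.4, tau_lit = 2, tau_s0 = 35)
  run <- run_scenario(p, quiet_forcing(trend = 0), "S1")
  tau_agg <- diagnose_tau_s(aggregate_soil_pools(run), run$series$Rh)
  expect_lt(tau_agg[length(tau_agg)], tau_agg[1])
})

test_that("ensemble sampling is reproducible and range-contained", {
  e1 <- generate_ensemble(5, seed = 42)
  e2 <- generate_ensemble(5, seed = 42)
  expect_identical(e1$param_table, e2$param_table)
  expect_length(e1$quartets, 5)
  rng <- default_param_ranges()
  for (nm in names(rng)) {
    expect_true(all(e1$param_table[[nm]] >= rng[[nm]][1] &
                    e1$param_table[[nm]] <= rng[[nm]][2]))
  }
  # flag constraints: cwd/litter-in-soil only where litter exists
  with(e1$param_table, {
    expect_true(all(!has_cwd | has_litter))
    expect_true(all(!litter_in_soil | has_litter))
  })
  expect_error(generate_ensemble(1, seed = 1), ">= 2")
  expect_error(generate_ensemble(3, ranges = list(beta = c(2, 1)),
                                 seed = 1),
               "empty")
})

test_that("degenerate parameter ranges collapse ensemble spread to zero", {
  rng <- lapply(default_param_ranges(), function(r) rep(mean(r), 2))
  e <- generate_ensemble(3, ranges = rng,
                         flag_probs = c(has_litter = 1, has_cwd = 0,
                                        litter_in_soil = 0),
                         seed = 9)
  dcv <- vapply(e$quartets, function(q) {
    s <- q$runs$S3$series
    s$cVeg[nrow(s)] - s$cVeg[1]
  }, numeric(1))
  expect_equal(sd(dcv), 0)
})
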