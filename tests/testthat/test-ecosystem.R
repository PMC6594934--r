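test_that("production respects nutrient limitation and the diazotroph rules", {
  p <- ecosystem_params()
  expect_equal(ordinary_production(0, 1, 20, p), 0)     # no nitrate
  expect_equal(ordinary_production(10, 0, 20, p), 0)    # no phosphate
  # saturation limit: rate -> mu_max * biomass proxy
  expect_equal(ordinary_production(1e6, 1e6, 20, p),
               p$mu_max_phy * p$biomass_proxy, tolerance = 1e-4)
  # diazotrophs: zero strictly below the temperature cutoff
  expect_equal(diazotroph_production(1.0, 14.9, p), 0)
  expect_gt(diazotroph_production(1.0, 15.0, p), 0)     # hard step, not a ramp
  expect_equal(diazotroph_production(0, 20, p), 0)
  # at saturation, diazotrophs run at less than half the ordinary rate
  expect_lt(diazotroph_production(1e6, 20, p),
            0.5 * ordinary_production(1e6, 1e6, 20, p))
  expect_error(ecosystem_params(mu_max_diaz = 25, mu_max_phy = 40),
               "less than half")
  expect_error(ecosystem_params(remin_partition = list(
    LowLatSurface = c(OMZ = 0.5, Deep = 0.4),
    SouthernOceanSurface = c(Deep = 1), NorthSurface = c(Deep = 1))),
    "sum to 1")
})

test_that("remineralisation switches oxidant at the suboxic threshold", {
  s <- stoich_params()
  one_orgN <- 1 / 16  # mol P carrying 1 mol organic N
  # aerobic: 10.6 mol O2 consumed per mol organic N
  r <- remineralize(one_orgN, o2 = 150, no3 = 30, s)
  expect_equal(-r$d_o2, 10.6)
  expect_equal(r$d_po4, one_orgN)
  expect_equal(r$denit_frac, 0)
  expect_equal(r$remainder, 0)
  # suboxic with ample nitrate: 7.48 mol NO3 consumed as electron acceptor
  # per mol organic N, no oxygen consumed
  r <- remineralize(one_orgN, o2 = 2, no3 = 30, s)
  expect_equal(r$d_o2, 0)
  expect_equal(r$denit_no3, 7.48)
  expect_equal(r$denit_frac, 1)
  # the nitrate tracer tendency nets the organic-N return
  expect_equal(-r$d_no3, 7.48 - 1)
  # nitrate exhausted: remineralisation stops, remainder reported
  r <- remineralize(one_orgN, o2 = 2, no3 = 0, s)
  expect_equal(r$d_o2, 0)
  expect_equal(r$d_no3, 0)
  expect_equal(r$d_po4, 0)
  expect_equal(r$remainder, one_orgN)
  # exactly at the threshold the pathway is aerobic ("below" switches)
  r <- remineralize(one_orgN, o2 = s$o2_threshold, no3 = 30, s)
  expect_equal(r$denit_frac, 0)
  expect_lt(r$d_o2, 0)
  expect_error(remineralize(-1, 100, 30, s), "non-negative")
})

test_that("capacity caps keep the pathway split within what the box holds", {
  s <- stoich_params()
  # aerobic consumption cannot drive O2 negative within the step
  r <- remineralize(1, o2 = 6, no3 = 50, s, vol = 1, dt = 1)
  expect_lte(-r$d_o2, 6)
  expect_gte(r$denit_frac, 0); expect_lte(r$denit_frac, 1)
  expect_equal(-r$d_o2 / s$r_o2p + r$denit_no3 / s$r_no3p + r$remainder, 1,
               tolerance = 1e-12)
  # suboxic: denitrification cannot drive NO3 negative
  r <- remineralize(1, o2 = 2, no3 = 10, s, vol = 1, dt = 1)
  expect_lte(-r$d_no3, 10)
  expect_gt(r$remainder, 0)
})

test_that("surface NCP removes nutrients at Redfield ratios", {
  p <- ecosystem_params()
  s <- stoich_params()
  # zero production, zero export
  out <- ncp(0, 0, 22, 3e16, p, s)
  expect_equal(out$export_p, 0)
  expect_equal(out$d_o2, 0)
  # diazotroph-only production: new organic N, surface nitrate untouched
  out <- ncp(0, 1.5, 22, 3e16, p, s)
  expect_equal(out$export_ord, 0)
  expect_gt(out$export_diaz, 0)
  expect_equal(out$d_no3, 0)
  expect_equal(out$fixation_n, s$r_np * out$export_diaz)
  # mixed production exports N:P = 16 exactly and draws PO4 1:1
  out <- ncp(5, 1.0, 22, 3e16, p, s)
  orgN <- s$r_np * out$export_p
  expect_equal(orgN / out$export_p, 16)
  expect_equal(-out$d_po4, out$export_p)
  expect_equal(-out$d_no3, s$r_np * out$export_ord)
})

test_that("closed nitrogen-fixation and denitrification loops balance as designed", {
  s <- stoich_params()
  p <- ecosystem_params()
  # fixation -> export -> aerobic remineralisation, per mol P:
  # net NO3 +16 (one mole per mole fixed N), net O2 = -(r_o2p/r_no3p)*16
  # (the nitrification debt of the newly fixed nitrogen; fixation is an
  # oxygen sink for the ocean)
  out <- ncp(0, 2.0, 25, 1e16, p, s)            # diazotroph-only
  rem <- remineralize(out$export_p, o2 = 200, no3 = 30, s)
  net_o2_per_p <- (out$d_o2 + rem$d_o2) / out$export_p
  net_no3_per_p <- (out$d_no3 + rem$d_no3) / out$export_p
  expect_equal(net_no3_per_p, s$r_np)
  expect_equal(net_o2_per_p, -s$r_np * o2_per_no3_lost(s), tolerance = 1e-12)
  expect_equal(net_o2_per_p / s$r_np, -1.417, tolerance = 1e-3)
  # ordinary production -> export -> denitrification, per mol organic N:
  # net O2 +10.6 avoided relative to aerobic, net NO3 -7.48
  out <- ncp(20, 2.0, 10, 1e16, p, s)           # cold: no diazotrophs
  expect_equal(out$export_diaz, 0)
  rem <- remineralize(out$export_p, o2 = 2, no3 = 40, s)
  net_no3_per_n <- (out$d_no3 + rem$d_no3) / (s$r_np * out$export_p)
  expect_equal(net_no3_per_n, -no3_demand_per_orgN(s), tolerance = 1e-12)
  # oxygen: production released r_o2p, denitrification consumed none
  expect_equal((out$d_o2 + rem$d_o2) / out$export_p, s$r_o2p)
  # and the ordinary aerobic loop is exactly oxygen- and nitrogen-neutral
  rem_a <- remineralize(out$export_p, o2 = 200, no3 = 40, s)
  expect_equal(out$d_o2 + rem_a$d_o2, 0, tolerance = 1e-9)
  expect_equal(out$d_no3 + rem_a$d_no3, 0, tolerance = 1e-9)
})

test_that("raising the diazotroph cutoff above all temperatures silences fixation", {
  cfg <- ox_config(ecosystem = ecosystem_params(temp_cutoff_diaz = 99))
  st <- init_state(cfg)
  run <- run_simulation(cfg, st, years = 300)
  expect_equal(run$fluxes$fixation_n, 0)
  expect_equal(max(abs(run$globals$fixation_rate)), 0)
})
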