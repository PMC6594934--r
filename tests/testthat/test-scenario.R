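test_that("null scenario gives zero anomalies and unit overturning", {
  g <- box_geometry()
  frc <- make_warming_scenario(scenario_params(d_t_ocean = 0), g)
  expect_equal(max(abs(frc$temp_anomaly)), 0)
  expect_equal(frc$psi_factor, rep(1, length(frc$years)))
  ctl <- make_control_scenario(geometry = g)
  expect_equal(max(abs(ctl$temp_anomaly)), 0)
  expect_equal(ctl$psi_factor, rep(1, length(ctl$years)))
})

test_that("volume-weighted warming hits the prescribed peak exactly", {
  g <- box_geometry()
  p <- scenario_params()
  frc <- make_warming_scenario(p, g)
  w <- g$volumes / sum(g$volumes)
  at_peak <- frc$temp_anomaly[match(p$t_peak, frc$years), ]
  expect_equal(sum(w * at_peak), 3.1, tolerance = 1e-6)
  # anomalies start at zero and the surface leads the deep
  expect_equal(max(abs(frc$temp_anomaly[1, ])), 0, tolerance = 1e-12)
  half <- apply(frc$temp_anomaly, 2, function(a)
    frc$years[which(a >= 0.5 * a[length(a)])[1]])
  expect_lt(half["LowLatSurface"], half["Deep"])
  # the Southern Ocean surface stays below the diazotroph cutoff throughout
  expect_true(all(4 + frc$temp_anomaly[, "SouthernOceanSurface"] < 15))
})

test_that("overturning dips before year 2500 and ends slightly above one", {
  frc <- make_warming_scenario(geometry = box_geometry())
  i_min <- which.min(frc$psi_factor)
  expect_lt(frc$psi_factor[i_min], 1)
  expect_lt(frc$years[i_min], 2500)
  expect_gt(frc$psi_factor[length(frc$psi_factor)], 1)
  expect_true(all(frc$psi_factor > 0))
  # the post-recovery maximum sits near year 3080
  late <- frc$years > 2600
  expect_lt(abs(frc$years[late][which.max(frc$psi_factor[late])] - 3080), 200)
})

test_that("scenario generation is deterministic and timing errors are caught", {
  g <- box_geometry()
  a <- make_warming_scenario(scenario_params(), g, seed = 1)
  b <- make_warming_scenario(scenario_params(), g, seed = 999)
  expect_identical(a$temp_anomaly, b$temp_anomaly)  # no noise by default
  expect_identical(a$psi_factor, b$psi_factor)
  n1 <- make_warming_scenario(scenario_params(noise_sd = 0.05), g, seed = 7)
  n2 <- make_warming_scenario(scenario_params(noise_sd = 0.05), g, seed = 7)
  n3 <- make_warming_scenario(scenario_params(noise_sd = 0.05), g, seed = 8)
  expect_identical(n1$temp_anomaly, n2$temp_anomaly)
  expect_false(identical(n1$temp_anomaly, n3$temp_anomaly))
  expect_error(scenario_params(t_peak = 1700), "inconsistent timing")
  expect_error(scenario_params(year_end = 1800), "after it starts")
  expect_error(scenario_params(moc_dip_depth = 1.2), "positive")
})

test_that("forcing round-trips through CSV", {
  frc <- make_warming_scenario(geometry = box_geometry())
  path <- tempfile(fileext = ".csv")
  write_forcing_csv(frc, path)
  back <- read_forcing_csv(path)
  expect_equal(back$years, frc$years)
  expect_equal(unname(back$temp_anomaly), unname(frc$temp_anomaly),
               tolerance = 1e-12)
  expect_equal(back$psi_factor, frc$psi_factor, tolerance = 1e-12)
  unlink(path)
})

test_that("control-forced run from the spun state stays flat", {
  run <- control_run()
  g <- run$globals
  expect_lt(max(g$o2_inv) - min(g$o2_inv), 0.05)
  expect_lt(max(g$no3_inv) - min(g$no3_inv), 0.05)
  expect_lt(max(g$po4_inv) - min(g$po4_inv), 1e-6)
  rep <- report(run)
  expect_true(rep$flat)
})

test_that("control and warming runs diverge only after the forcing does", {
  # the scenario's anomalies are zero at the start year by construction,
  # so the first decades stay within the control flicker envelope
  gw <- warming_run()$globals
  gc <- control_run()$globals
  early <- gw$time <= 1856
  expect_lt(max(abs(gw$o2_inv[early] - gc$o2_inv[early])), 0.05)
  late <- gw$time >= 3000
  expect_gt(max(abs(gw$o2_inv[late] - gc$o2_inv[late])), 1)
})
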