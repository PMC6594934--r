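test_that("configuration validation catches cross-module inconsistencies", {
  expect_error(ox_config(dt = -0.1), "dt > 0")
  expect_error(ox_config(dt = 0.3, output_every = 1), "multiple of dt")
  bad_eco <- ecosystem_params(remin_partition = list(
    LowLatSurface = c(NorthSurface = 1),  # a surface box cannot receive export
    SouthernOceanSurface = c(Deep = 1), NorthSurface = c(Deep = 1)))
  expect_error(ox_config(ecosystem = bad_eco), "non-interior")
})

test_that("single steps conserve phosphorus and report flux integrals", {
  cfg <- default_config()
  st <- init_state(cfg)
  V <- cfg$geometry$volumes
  p0 <- sum(V * st$conc[, "po4"])
  st1 <- step_model(st, cfg)
  expect_equal(sum(V * st1$conc[, "po4"]) / p0, 1, tolerance = 1e-13)
  fl <- attr(st1, "fluxes")
  expect_true(all(c("airsea", "fixation_n", "denit_n", "ncp_p") %in% names(fl)))
  expect_gt(fl$ncp_p, 0)
  expect_error(step_model(st, cfg, dt = 0), "positive")
})

test_that("a spun-up state barely moves under zero forcing anomaly", {
  cfg <- default_config()
  st <- spun_state()
  st1 <- step_model(st, cfg)
  rel <- abs(st1$conc - st$conc) / (abs(st$conc) + 1e-2)
  # per-step relative motion is within the threshold-flicker envelope
  expect_lt(max(rel), 5e-3)
  expect_lt(stats::median(rel), 1e-5)
})

test_that("phosphorus is conserved over a multi-millennial run", {
  # 6000 model years at the default dt = 0.05 from a cold start
  cfg <- default_config()
  run <- cached("run6000", run_simulation(cfg, init_state(cfg), years = 6000))
  p <- run$globals$po4_inv
  expect_lt(max(abs(p - p[1])) / p[1], 1e-10)
})

test_that("fixed-nitrogen bookkeeping closes: dNO3 = fixation - denitrification", {
  run <- cached("run6000", run_simulation(default_config(),
                                          init_state(default_config()),
                                          years = 6000))
  g <- run$globals
  n0 <- sum(default_config()$geometry$volumes *
              init_state(default_config())$conc[, "no3"]) * 1e-18
  lhs <- g$no3_inv - n0
  rhs <- g$cum_fixation - g$cum_denit
  expect_lt(max(abs(lhs - rhs)) / g$no3_inv[1], 1e-10)
})

test_that("spin-up converges to a steady oxygenated ocean and is idempotent", {
  st <- spun_state()
  conv <- attr(st, "convergence")
  expect_true(conv$converged)
  expect_lt(conv$residual, conv$tol)
  expect_true(all(st$conc[, "o2"] > 0))
  expect_true(all(st$conc[, c("no3", "po4")] >= 0))
  # re-entering spin-up from the converged state exits at the first
  # opportunity with an essentially unchanged state
  cfg <- default_config()
  again <- spinup(cfg, state = st, check_every = 100)
  expect_lte(attr(again, "convergence")$years, 200)
  expect_equal(again$conc, st$conc, tolerance = 5e-3)
  # non-convergence carries the residual in the error
  expect_error(spinup(cfg, tol = 1e-14, max_years = 600), "did not converge")
})

test_that("halving the step does not move the budget decomposition", {
  cfg <- default_config()
  st <- spun_state()
  frc <- warming_forcing()
  run_a <- run_simulation(cfg, st, frc, years = 400, dt = 0.05)
  run_b <- run_simulation(cfg, st, frc, years = 400, dt = 0.025)
  ba <- decompose_budget(run_a)
  bb <- decompose_budget(run_b)
  expect_lt(abs(ba$d_o2 - bb$d_o2), 0.05)
  expect_lt(abs(ba$airsea_flux - bb$airsea_flux), 0.05)
  expect_lt(abs(ba$d_no3 - bb$d_no3), 0.05)
})

test_that("identical configuration and forcing reproduce identical output", {
  cfg <- default_config()
  st <- spun_state()
  frc <- warming_forcing()
  r1 <- run_simulation(cfg, st, frc, years = 120)
  r2 <- run_simulation(cfg, st, frc, years = 120)
  expect_identical(r1$globals, r2$globals)
  expect_identical(r1$conc, r2$conc)
})
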