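test_that("preformed phosphate equals PO4 in surface boxes after every step", {
  cfg <- default_config()
  st <- spun_state()
  surf <- cfg$geometry$is_surface
  expect_equal(st$conc[surf, "po4_pre"], st$conc[surf, "po4"])
  # and after an arbitrary forced step
  st2 <- step_model(st, cfg, forcing_at_t = list(
    temp_anomaly = rep(1, cfg$geometry$n_boxes), psi_factor = 0.8))
  expect_equal(st2$conc[surf, "po4_pre"], st2$conc[surf, "po4"])
  # standalone reset does the same thing
  st3 <- update_preformed_po4(st2, cfg$geometry)
  expect_equal(st3$conc, st2$conc)
})

test_that("TOU is the stoichiometric oxygen equivalent of regenerated PO4", {
  s <- stoich_params()
  g <- box_geometry()
  st <- init_state(ox_config())
  st$conc[, "po4"] <- 2.0
  st$conc[, "po4_pre"] <- 1.5
  out <- tou(st, s, g)
  expect_equal(unname(out$per_box), rep(0.5 * 169.6, g$n_boxes))
  expect_equal(out$global, sum(g$volumes) * 84.8 * 1e-18)
  st$conc[, "po4_pre"] <- st$conc[, "po4"]
  expect_equal(tou(st, s, g)$global, 0)
  # regenerated phosphate is non-negative everywhere in a real run
  run <- warming_run()
  expect_true(all(run$conc[, , "po4"] - run$conc[, , "po4_pre"] > -1e-9))
})

test_that("with biology off, O2 and abiotic O2 are identical to 1e-12", {
  cfg <- two_box_config(biology = FALSE)
  run <- run_simulation(cfg, init_state(cfg), years = 500)
  expect_lt(max(abs(run$conc[, , "o2"] - run$conc[, , "o2_abio"])), 1e-12)
  # and preformed PO4 equals PO4 everywhere: nothing regenerates
  expect_lt(max(abs(run$conc[, , "po4"] - run$conc[, , "po4_pre"])), 1e-12)
})

test_that("a warming step lowers the abiotic oxygen inventory", {
  cfg <- two_box_config(biology = FALSE)
  run0 <- run_simulation(cfg, init_state(cfg), years = 800)
  st <- run0$final_state
  warm <- list(temp_anomaly = c(3, 3), psi_factor = 1)
  st2 <- st
  for (i in 1:200) st2 <- step_model(st2, cfg, forcing_at_t = warm, dt = 0.05)
  V <- cfg$geometry$volumes
  expect_lt(sum(V * st2$conc[, "o2_abio"]), sum(V * st$conc[, "o2_abio"]))
  # warming-only: O2 and abiotic decline identically (no biology)
  expect_equal(sum(V * (st2$conc[, "o2"] - st$conc[, "o2"])),
               sum(V * (st2$conc[, "o2_abio"] - st$conc[, "o2_abio"])),
               tolerance = 1e-12)
})

test_that("spun-up interior abiotic O2 is surface saturation propagated by transport", {
  # two-box reduction: the deep box holds exactly the saturation of the
  # only surface box it exchanges with
  cfg <- two_box_config(biology = FALSE)
  run <- run_simulation(cfg, init_state(cfg), years = 1500)
  sat_surf <- o2_saturation(cfg$geometry$temperatures[1], cfg$gasex$salinity)
  expect_equal(run$final_state$conc["Deep", "o2_abio"], sat_surf,
               tolerance = 1e-4)
  # full geometry at spin-up: surface abiotic O2 within the gas-exchange
  # disequilibrium tolerance of local saturation
  st <- spun_state()
  g <- default_config()$geometry
  sat <- o2_saturation(g$temperatures[g$is_surface])
  expect_equal(unname(st$conc[g$is_surface, "o2_abio"]), unname(sat),
               tolerance = 0.01)
})

test_that("AOU differs from TOU by the surface-disequilibrium bias", {
  st <- spun_state()
  cfg <- default_config()
  a <- aou(st)
  t_ <- tou(st, cfg$stoich, cfg$geometry)$per_box
  # same order of magnitude in the interior, but not equal
  int <- !cfg$geometry$is_surface
  expect_true(all(a[int] > 0))
  expect_false(isTRUE(all.equal(unname(a[int]), unname(t_[int]))))
})
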