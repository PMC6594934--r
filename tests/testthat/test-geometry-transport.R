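test_that("transport of a uniform field has zero tendency everywhere", {
  g <- box_geometry()
  circ <- circulation_scheme()
  tend <- transport_tendency(rep(3.2, g$n_boxes), g, circ)
  expect_lt(max(abs(tend)), 1e-12)  # exact up to rounding
})

test_that("two-box exchange follows the closed form psi * dC / V", {
  g <- box_geometry(volumes = c(A = 2e16, B = 8e16),
                    surface_areas = c(A = 1e14),
                    temperatures = c(A = 10, B = 3))
  circ <- circulation_scheme(psi = 5e14, loop = c("A", "B"), mixing = list())
  tend <- transport_tendency(c(1, 0), g, circ)
  expect_equal(tend[1], 5e14 * (0 - 1) / 2e16)
  expect_equal(tend[2], 5e14 * (1 - 0) / 8e16)
})

test_that("random conservative circulations conserve every tracer inventory", {
  set.seed(42)
  g <- box_geometry()
  for (i in 1:20) {
    labs <- g$labels
    loop <- sample(labs, sample(3:g$n_boxes, 1))
    pairs <- t(combn(labs, 2))
    pick <- sample(nrow(pairs), 4)
    mixing <- stats::setNames(
      as.list(stats::runif(4, 0, 1e15)),
      apply(pairs[pick, , drop = FALSE], 1, paste, collapse = "|"))
    circ <- circulation_scheme(psi = stats::runif(1, 0, 1e15),
                               loop = loop, mixing = mixing)
    conc <- matrix(stats::runif(g$n_boxes * 3, 0, 40), g$n_boxes)
    tend <- transport_tendency(conc, g, circ, psi_factor = stats::runif(1, 0.4, 1.6))
    drift <- colSums(g$volumes * tend) / colSums(g$volumes * conc)
    expect_lt(max(abs(drift)), 1e-12)
  }
})

test_that("overturning scale factor multiplies only the loop limb", {
  g <- box_geometry()
  circ <- circulation_scheme()
  conc <- matrix(seq_len(g$n_boxes * 2), g$n_boxes)
  t1 <- transport_tendency(conc, g, circ, psi_factor = 1)
  t2 <- transport_tendency(conc, g, circ, psi_factor = 2)
  no_mix <- circulation_scheme(psi = circ$psi, loop = circ$loop, mixing = list())
  tp <- transport_tendency(conc, g, no_mix, psi_factor = 1)
  expect_equal(t2 - t1, tp, tolerance = 1e-12)
})

test_that("geometry and circulation invariants are enforced", {
  expect_error(box_geometry(volumes = c(A = -1, B = 1),
                            surface_areas = c(A = 1),
                            temperatures = c(A = 1, B = 1)), "positive")
  expect_error(box_geometry(volumes = c(A = 1e15, B = 1e15),
                            surface_areas = c(A = 1e13, B = 1e13),
                            temperatures = c(A = 1, B = 1)),
               "at least one surface and one interior")
  expect_error(circulation_scheme(psi = -1), "non-negative")
  expect_error(
    transport_tendency(c(1, 0), box_geometry(
      volumes = c(A = 2e16, B = 8e16), surface_areas = c(A = 1e14),
      temperatures = c(A = 10, B = 3)),
      circulation_scheme(psi = 1e14, loop = c("A", "Nowhere"), mixing = list())),
    "unknown box")
})

test_that("ideal age reaches the analytic V/psi steady state in two boxes", {
  psi <- 1e15; v_deep <- 1e17
  cfg <- two_box_config(psi = psi, v_deep = v_deep)
  run <- run_simulation(cfg, init_state(cfg), years = 1500)
  age_deep <- run$final_state$conc["Deep", "age"]
  expect_equal(age_deep, v_deep / psi, tolerance = 1e-3)
  expect_equal(run$final_state$conc["Surface", "age"], 0)
  # faster overturning: younger interior (the psi -> infinity limit is 0)
  cfg_fast <- two_box_config(psi = 10 * psi, v_deep = v_deep)
  run_fast <- run_simulation(cfg_fast, init_state(cfg_fast), years = 300)
  expect_equal(run_fast$final_state$conc["Deep", "age"],
               v_deep / (10 * psi), tolerance = 1e-3)
})

test_that("without transport the interior ages at one year per year", {
  cfg <- two_box_config(psi = 0)
  st <- init_state(cfg)
  run <- run_simulation(cfg, st, years = 50)
  expect_equal(run$final_state$conc["Deep", "age"], 50, tolerance = 1e-9)
})
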