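# Shared expensive fixtures, computed lazily once per test session.
# Everything is deterministic (the model has no stochastic component with
# the default noise-free scenario).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

default_config <- function() cached("config", ox_config())

spun_state <- function() cached("spun", spinup(default_config()))

warming_forcing <- function() cached(
  "warm_frc", make_warming_scenario(geometry = default_config()$geometry))

warming_run <- function() cached(
  "warm_run",
  run_simulation(default_config(), spun_state(), warming_forcing()))

control_run <- function() cached(
  "ctrl_run",
  run_simulation(default_config(), spun_state(),
                 make_control_scenario(geometry = default_config()$geometry)))

counterfactual_run <- function() cached(
  "cf_run",
  run_simulation(instant_fixation_config(default_config()), spun_state(),
                 warming_forcing()))

# Minimal two-box ocean (surface + deep, overturning only) for the
# closed-form oracles: ideal age V/psi, abiotic saturation propagation,
# biology-off tracer identity.
two_box_config <- function(psi = 1e15, v_deep = 1e17, biology = FALSE,
                           pv = 1200, dt = 0.05) {
  ox_config(
    geometry = box_geometry(
      volumes = c(Surface = 5e15, Deep = v_deep),
      surface_areas = c(Surface = 1e14),
      temperatures = c(Surface = 12, Deep = 3)),
    circulation = circulation_scheme(psi = psi, loop = c("Surface", "Deep"),
                                     mixing = list()),
    ecosystem = ecosystem_params(
      prod_scale = c(Surface = if (biology) 1 else 0),
      remin_partition = list(Surface = c(Deep = 1)),
      fixation_enabled = FALSE,
      remin_t_sens = 0),
    gasex = gasex_params(piston_velocity = pv),
    dt = dt,
    init = list(o2 = NULL, no3 = c(8, 30), po4 = c(0.8, 2.2)))
}

# Default-geometry configuration kept aerobic everywhere: production scaled
# down so no interior box approaches the suboxic threshold, nitrogen
# imbalance processes off. Used for the budget identities that presume a
# purely aerobic ocean.
aerobic_config <- function(pv = 1200) {
  ox_config(
    ecosystem = ecosystem_params(
      prod_scale = c(LowLatSurface = 0.35, SouthernOceanSurface = 0.1,
                     NorthSurface = 0.2),
      fixation_enabled = FALSE, denitrification_enabled = FALSE,
      remin_t_sens = 0),
    gasex = gasex_params(piston_velocity = pv))
}
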