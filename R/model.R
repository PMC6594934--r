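# Tracer column layout of the state matrix (boxes x tracers)
TR_O2 <- 1L; TR_NO3 <- 2L; TR_PO4 <- 3L; TR_PRE <- 4L; TR_ABIO <- 5L; TR_AGE <- 6L
TRACER_NAMES <- c("o2", "no3", "po4", "po4_pre", "o2_abio", "age")
PMOL_PER_MMOL <- 1e-18  # 1 Pmol = 1e15 mol = 1e18 mmol

#' Model configuration
#'
#' Bundles geometry, circulation, stoichiometry, ecosystem, gas exchange and
#' integration settings, validated against all module invariants before any
#' run starts. Time integration is fixed-step forward Euler (transparent,
#' exact flux bookkeeping for budget closure) with `dt <= 0.05` yr by
#' default; gas exchange is applied as an exact within-step relaxation so
#' the piston-velocity to infinity limit is well posed.
#'
#' Per-step order of operations: transport, biology, gas exchange,
#' preformed-phosphate reset (surface preformed PO4 set identical to PO4),
#' matching the tracer definitions.
#'
#' @param geometry an [box_geometry()].
#' @param circulation an [circulation_scheme()].
#' @param stoich an [stoich_params()].
#' @param ecosystem an [ecosystem_params()].
#' @param gasex an [gasex_params()].
#' @param dt integration step, yr.
#' @param output_every output/diagnostic interval, yr (multiple of `dt`).
#' @param spinup_tol spin-up convergence tolerance: maximum relative change
#'   per year of the chunk-averaged state (see [spinup()]).
#' @param spinup_max_years cap on spin-up length.
#' @param spinup_coarse_dt larger step used for the bulk of the spin-up
#'   before polishing at `dt`.
#' @param budget_tol budget-closure tolerance in Pmol (scales with `dt`).
#' @param init named list of initial per-box concentration vectors
#'   (`o2`, `no3`, `po4` in mmol m^-3); abiotic O2 starts equal to O2,
#'   preformed PO4 equal to PO4 and ideal age at zero.
#' @return An `ox_config` list.
#' @export
ox_config <- function(geometry = box_geometry(),
                      circulation = circulation_scheme(),
                      stoich = stoich_params(),
                      ecosystem = ecosystem_params(),
                      gasex = gasex_params(),
                      dt = 0.05,
                      output_every = 1,
                      spinup_tol = 1e-6,
                      spinup_max_years = 60000,
                      spinup_coarse_dt = 0.2,
                      budget_tol = 0.01,
                      init = list(o2 = NULL,
                                  no3 = c(8, 25, 12, 30, 30, 32),
                                  po4 = c(0.8, 1.7, 1.0, 2.2, 2.2, 2.3))) {
  cfg <- list(geometry = geometry, circulation = circulation,
              stoich = stoich, ecosystem = ecosystem, gasex = gasex,
              integration = list(dt = dt, output_every = output_every,
                                 spinup_tol = spinup_tol,
                                 spinup_max_years = spinup_max_years,
                                 spinup_coarse_dt = spinup_coarse_dt,
                                 budget_tol = budget_tol),
              init = init)
  class(cfg) <- "ox_config"
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Re-runs every module's invariant checks and the cross-module consistency
#' checks (circulation conservativity on the configured geometry, partition
#' targets exist, integration settings sane).
#'
#' @param cfg an `ox_config`.
#' @return the configuration, invisibly; errors on any violation.
#' @export
validate_config <- function(cfg) {
  validate_stoich(cfg$stoich)
  validate_ecosystem(cfg$ecosystem)
  g <- cfg$geometry
  build_transport(g, cfg$circulation)  # errors if non-conservative
  surf <- g$labels[g$is_surface]
  if (!all(surf %in% names(cfg$ecosystem$prod_scale)))
    stop("prod_scale must cover every surface box")
  if (!all(surf %in% names(cfg$ecosystem$remin_partition)))
    stop("remin_partition must cover every surface box")
  for (s in surf) {
    tgt <- names(cfg$ecosystem$remin_partition[[s]])
    if (!all(tgt %in% g$labels[!g$is_surface]))
      stop("remineralisation partition of ", s, " targets a non-interior box")
  }
  it <- cfg$integration
  if (it$dt <= 0 || it$output_every < it$dt)
    stop("need dt > 0 and output_every >= dt")
  if (abs(it$output_every / it$dt - round(it$output_every / it$dt)) > 1e-8)
    stop("output_every must be a multiple of dt")
  invisible(cfg)
}

#' Initial ocean state
#'
#' Builds the state matrix from the configured initial concentrations:
#' surface O2 defaults to saturation at the pre-industrial box temperature,
#' abiotic O2 starts identical to O2, preformed PO4 identical to PO4 and
#' ideal age at zero.
#'
#' @param config an [ox_config()].
#' @return An `ox_state`: list with `time` (yr), `conc` (boxes x tracers
#'   matrix, mmol m^-3 except age in yr) and `temp` (degC per box).
#' @export
init_state <- function(config) {
  g <- config$geometry
  n <- g$n_boxes
  o2 <- config$init$o2
  if (is.null(o2)) {
    o2 <- rep(100, n)
    o2[g$is_surface] <- o2_saturation(g$temperatures[g$is_surface],
                                      config$gasex$salinity)
    o2[g$labels == "OMZ"] <- 20
    o2[g$labels == "Thermocline"] <- 60
    o2[g$labels == "Deep"] <- 160
  }
  conc <- cbind(o2 = o2, no3 = config$init$no3, po4 = config$init$po4,
                po4_pre = config$init$po4, o2_abio = o2, age = rep(0, n))
  rownames(conc) <- g$labels
  structure(list(time = 0, conc = conc, temp = g$temperatures),
            class = "ox_state")
}

# ---- engine -----------------------------------------------------------

# Precompute everything the inner loop needs as flat vectors/matrices.
compile_engine <- function(config) {
  g <- config$geometry
  e <- config$ecosystem
  s <- config$stoich
  op <- build_transport(g, config$circulation)
  surf <- which(g$is_surface)
  interior <- which(!g$is_surface)
  # interior boxes ordered shallow-to-deep (by volume as proxy) so the
  # unremineralised remainder cascades downstream and is finally dumped
  # into the last (deep) box
  interior <- interior[order(g$volumes[interior])]
  W <- matrix(0, length(surf), length(interior),
              dimnames = list(g$labels[surf], g$labels[interior]))
  for (i in seq_along(surf)) {
    part <- e$remin_partition[[g$labels[surf[i]]]]
    W[i, names(part)] <- part
  }
  ll <- match("LowLatSurface", g$labels[surf])  # box whose warming drives shallowing
  shallow_col <- match("Thermocline", colnames(W))
  if (is.na(shallow_col)) shallow_col <- match("OMZ", colnames(W))
  list(n = g$n_boxes, V = g$volumes, surf = surf, interior = interior,
       A = g$surface_areas[surf], temp0 = g$temperatures,
       Mpsi = op$Mpsi, Mmix = op$Mmix,
       W = W, ll_row = ll, shallow_col = shallow_col,
       scale = unname(e$prod_scale[g$labels[surf]]),
       mu_phy = e$mu_max_phy, mu_diaz = e$mu_max_diaz,
       k_no3 = e$k_no3, k_po4 = e$k_po4, k_diaz = e$k_po4_diaz,
       t_cut = e$temp_cutoff_diaz, b0 = e$biomass_proxy,
       ef = e$export_frac, t_sens = e$remin_t_sens,
       fix_on = e$fixation_enabled, den_on = e$denitrification_enabled,
       comp_on = isTRUE(e$fixation_compensating),
       r_o2p = s$r_o2p, r_np = s$r_np, r_no3p = s$r_no3p,
       no3_net = s$r_no3p - s$r_np, thr = s$o2_threshold,
       o2_rel_ord = o2_release_per_p(s, FALSE),
       o2_rel_diaz = o2_release_per_p(s, TRUE),
       pv = config$gasex$piston_velocity, sal = config$gasex$salinity)
}

# forcing interpolated onto the step grid; returns list(Tanom, psi) with
# one row per step (values at step start)
forcing_on_steps <- function(forcing, t0, nsteps, dt, eng) {
  tt <- t0 + (seq_len(nsteps) - 1) * dt
  nb <- eng$n
  Ta <- matrix(0, nsteps, nb)
  psi <- rep(1, nsteps)
  if (!is.null(forcing)) {
    yrs <- forcing$years
    tc <- pmin(pmax(tt, min(yrs)), max(yrs))
    for (b in seq_len(nb))
      Ta[, b] <- stats::approx(yrs, forcing$temp_anomaly[, b], tc)$y
    psi <- stats::approx(yrs, forcing$psi_factor, tc)$y
  }
  list(Ta = Ta, psi = psi)
}

# ---- the integrator ---------------------------------------------------

#' Advance the model state by one step
#'
#' One forward-Euler step of all tracers: transport, biology (production,
#' export, remineralisation with the aerobic/denitrification switch), gas
#' exchange for O2 and abiotic O2, ideal-age aging and surface reset, and
#' the preformed-PO4 surface reset, with all diagnostic flux integrals
#' accumulated exactly. Total phosphorus is conserved to rounding.
#'
#' This is the reference single-step interface; [run_simulation()] runs the
#' same core over a whole forcing trajectory.
#'
#' @param state an [init_state()]-shaped `ox_state`.
#' @param config an [ox_config()].
#' @param forcing_at_t list with `temp_anomaly` (per box, degC) and
#'   `psi_factor` (scalar); defaults to pre-industrial.
#' @param dt step length, yr.
#' @return the new `ox_state`; attribute `"fluxes"` carries the step's
#'   integrated diagnostic fluxes (mmol): `airsea`, `airsea_abio`,
#'   `fixation_n`, `denit_n`, `ncp_p`, `aerobic_p`, `denit_p`,
#'   `remainder_p`, `clipped`.
#' @export
step_model <- function(state, config, forcing_at_t = NULL, dt = config$integration$dt) {
  if (dt <= 0) stop("dt must be positive")
  eng <- compile_engine(config)
  Ta <- if (is.null(forcing_at_t)) rep(0, eng$n) else forcing_at_t$temp_anomaly
  psi <- if (is.null(forcing_at_t)) 1 else forcing_at_t$psi_factor
  acc <- new_acc()
  C <- step_core(state$conc, eng$temp0 + Ta, psi, eng, dt, acc)
  if (any(!is.finite(C)))
    stop("NaN in tendency at t = ", state$time, "; state dump:\n",
         paste(utils::capture.output(print(state$conc)), collapse = "\n"))
  out <- structure(list(time = state$time + dt, conc = C,
                        temp = eng$temp0 + Ta), class = "ox_state")
  attr(out, "fluxes") <- as.list(acc)
  out
}

new_acc <- function() {
  as.environment(list(airsea = 0, airsea_abio = 0, fixation_n = 0,
                      denit_n = 0, ncp_p = 0, aerobic_p = 0, denit_p = 0,
                      remainder_p = 0, clipped = 0))
}

# One Euler step on the raw concentration matrix. `acc` is an environment
# of flux accumulators (mmol). Kept free of S3 dispatch for speed.
step_core <- function(C, temp, psi_fac, eng, dt, acc) {
  V <- eng$V
  # transport (all tracers at once; zero column sums => exact conservation)
  M <- eng$Mmix + psi_fac * eng$Mpsi
  C <- C + (M %*% C) * (dt / V)
  # ideal age: interior aging, surface held at zero
  C[eng$interior, TR_AGE] <- C[eng$interior, TR_AGE] + dt
  C[eng$surf, TR_AGE] <- 0

  # --- biology: surface production and export --------------------------
  sb <- eng$surf
  no3 <- C[sb, TR_NO3]; po4 <- C[sb, TR_PO4]; Ts <- temp[sb]; Vs <- V[sb]
  lim <- pmin(no3 / (eng$k_no3 + no3), po4 / (eng$k_po4 + po4))
  e_ord <- eng$ef * eng$mu_phy * pmax(lim, 0) * eng$b0 * eng$scale * Vs
  if (eng$fix_on) {
    e_diaz <- eng$ef * eng$mu_diaz * pmax(po4, 0) / (eng$k_diaz + pmax(po4, 0)) *
      eng$b0 * eng$scale * Vs * (Ts >= eng$t_cut)
  } else e_diaz <- numeric(length(sb))
  # availability caps: nitrate first (ordinary only), then phosphate (both)
  cap_n <- pmin(1, no3 * Vs / pmax(eng$r_np * e_ord * dt, 1e-300))
  e_ord <- e_ord * cap_n
  cap_p <- pmin(1, po4 * Vs / pmax((e_ord + e_diaz) * dt, 1e-300))
  e_ord <- e_ord * cap_p; e_diaz <- e_diaz * cap_p
  C[sb, TR_NO3] <- no3 - eng$r_np * e_ord * dt / Vs
  C[sb, TR_PO4] <- po4 - (e_ord + e_diaz) * dt / Vs
  C[sb, TR_O2] <- C[sb, TR_O2] +
    (eng$o2_rel_ord * e_ord + eng$o2_rel_diaz * e_diaz) * dt / Vs
  acc$fixation_n <- acc$fixation_n + eng$r_np * sum(e_diaz) * dt
  acc$ncp_p <- acc$ncp_p + sum(e_ord + e_diaz) * dt

  # --- export partition, with optional warming-driven shallowing --------
  W <- eng$W
  if (eng$t_sens > 0 && !is.na(eng$ll_row) && !is.na(eng$shallow_col)) {
    dT_ll <- temp[sb[eng$ll_row]] - eng$temp0[sb[eng$ll_row]]
    if (dT_ll > 0) {
      w_ll <- W[eng$ll_row, ]
      w0 <- w_ll[eng$shallow_col]
      tgt <- min(0.98, w0 + eng$t_sens * dT_ll)
      if (tgt > w0 && w0 < 1) {
        w_ll <- w_ll * (1 - tgt) / (1 - w0)  # shrink the deeper shares
        w_ll[eng$shallow_col] <- tgt
        W[eng$ll_row, ] <- w_ll
      }
    }
  }
  Fint <- drop(crossprod(W, e_ord + e_diaz))  # mmol P yr^-1 per interior box

  # --- interior remineralisation, remainder cascading downstream --------
  carry <- 0
  acc_den <- 0  # this step's denitrified P, for the compensation mode
  for (k in seq_along(eng$interior)) {
    b <- eng$interior[k]
    Fb <- Fint[k] + carry
    if (Fb <= 0) { carry <- 0; next }
    o2b <- C[b, TR_O2]; no3b <- C[b, TR_NO3]; Vb <- V[b]
    if (!eng$den_on || o2b >= eng$thr) {
      aer <- min(Fb, max(o2b, 0) * Vb / (eng$r_o2p * dt))
    } else aer <- 0
    rest <- Fb - aer
    if (eng$den_on && rest > 0 && no3b > 0) {
      den <- min(rest, no3b * Vb / (eng$no3_net * dt))
    } else den <- 0
    carry <- Fb - aer - den
    C[b, TR_O2] <- o2b - eng$r_o2p * aer * dt / Vb
    C[b, TR_NO3] <- no3b + (eng$r_np * aer - eng$no3_net * den) * dt / Vb
    C[b, TR_PO4] <- C[b, TR_PO4] + (aer + den) * dt / Vb
    acc$aerobic_p <- acc$aerobic_p + aer * dt
    acc$denit_p <- acc$denit_p + den * dt
    acc$denit_n <- acc$denit_n + eng$r_no3p * den * dt
    acc_den <- acc_den + den
  }
  if (eng$comp_on) {
    # instantaneous compensation: top up the step's net fixed-N imbalance
    # as a uniform nitrate increment over the whole ocean (most of it in
    # the deep, where the escaped deficit resides), paying the
    # nitrification-equivalent O2 through the surface boxes
    comp <- eng$r_no3p * acc_den - eng$r_np * sum(e_diaz)
    C[, TR_NO3] <- C[, TR_NO3] + comp * dt / sum(V)
    C[sb, TR_O2] <- C[sb, TR_O2] -
      (eng$r_o2p / eng$r_no3p) * comp * dt / sum(V[sb])
    acc$fixation_n <- acc$fixation_n + comp * dt
  }
  if (carry > 0) {  # never remineralised: returned without oxidant demand
    b <- eng$interior[length(eng$interior)]
    C[b, TR_PO4] <- C[b, TR_PO4] + carry * dt / V[b]
    C[b, TR_NO3] <- C[b, TR_NO3] + eng$r_np * carry * dt / V[b]
    acc$remainder_p <- acc$remainder_p + carry * dt
  }

  # --- gas exchange (exact within-step relaxation), O2 and abiotic O2 ---
  sat <- o2_saturation(temp[sb], eng$sal)
  fac <- exp(-eng$pv * eng$A / V[sb] * dt)
  o2s <- C[sb, TR_O2]
  o2n <- sat + (o2s - sat) * fac
  C[sb, TR_O2] <- o2n
  acc$airsea <- acc$airsea + sum((o2n - o2s) * Vs)
  ab <- C[sb, TR_ABIO]
  abn <- sat + (ab - sat) * fac
  C[sb, TR_ABIO] <- abn
  acc$airsea_abio <- acc$airsea_abio + sum((abn - ab) * Vs)

  # --- preformed PO4: surface reset, otherwise purely passive -----------
  C[sb, TR_PRE] <- C[sb, TR_PO4]

  # --- non-negativity clipping (logged) ---------------------------------
  neg <- C[, 1:5] < 0
  if (any(neg)) {
    acc$clipped <- acc$clipped + sum(C[, 1:5][neg] * rep(V, 5)[neg])
    C[, 1:5][neg] <- 0
  }
  C
}

#' Integrate the model over a forcing trajectory
#'
#' Runs the fixed-step core from `state` under `forcing`, recording per-box
#' states and interval-integrated diagnostic fluxes every `output_every`
#' years. The unremineralised remainder must stay below 1 percent of
#' cumulative export or the run aborts (nitrate exhaustion is expected to
#' be rare and local, not systematic).
#'
#' @param config an [ox_config()].
#' @param state starting `ox_state` (e.g. from [spinup()]).
#' @param forcing an `ox_forcing` from [make_warming_scenario()] /
#'   [make_control_scenario()], or `NULL` for constant pre-industrial
#'   conditions.
#' @param years length of the run, yr; defaults to the forcing span.
#' @param dt override of the configured step, yr.
#' @return An `ox_run`: list with `times` (yr), `conc` (time x box x tracer
#'   array), `temp` (time x box), `globals` (data frame of inventories in
#'   Pmol, cumulative fluxes in Pmol, interval-mean rates in Tmol yr^-1,
#'   suboxic volume in m^3), `final_state`, `config`.
#' @export
run_simulation <- function(config, state, forcing = NULL, years = NULL,
                           dt = config$integration$dt) {
  eng <- compile_engine(config)
  if (is.null(years)) {
    if (is.null(forcing)) stop("give either a forcing or a run length")
    years <- max(forcing$years) - min(forcing$years)
  }
  t0 <- if (!is.null(forcing)) min(forcing$years) else state$time
  out_every <- config$integration$output_every
  steps_per_out <- round(out_every / dt)
  nout <- floor(years / out_every)
  nsteps <- nout * steps_per_out
  frc <- forcing_on_steps(forcing, t0, nsteps, dt, eng)

  C <- state$conc
  nb <- eng$n
  conc_out <- array(NA_real_, c(nout, nb, length(TRACER_NAMES)),
                    dimnames = list(NULL, rownames(C), TRACER_NAMES))
  temp_out <- matrix(NA_real_, nout, nb)
  gl <- matrix(0, nout, 16)
  colnames(gl) <- c("o2_inv", "no3_inv", "po4_inv", "abio_inv", "tou_inv",
                    "pre_inv", "cum_airsea", "cum_airsea_abio",
                    "cum_fixation", "cum_denit", "fixation_rate",
                    "denit_rate", "ncp_rate", "suboxic_vol", "mean_age",
                    "psi_factor")
  acc <- new_acc()
  cum <- c(airsea = 0, airsea_abio = 0, fix = 0, den = 0, ncp = 0, rem = 0)
  V <- eng$V
  step <- 0L
  for (r in seq_len(nout)) {
    prev <- c(acc$fixation_n, acc$denit_n, acc$ncp_p)
    for (k in seq_len(steps_per_out)) {
      step <- step + 1L
      C <- step_core(C, eng$temp0 + frc$Ta[step, ], frc$psi[step], eng, dt, acc)
    }
    if (any(!is.finite(C)))
      stop("NaN in tendency near t = ", t0 + step * dt, "; aborting with dump:\n",
           paste(utils::capture.output(print(C)), collapse = "\n"))
    tb <- eng$temp0 + frc$Ta[step, ]
    conc_out[r, , ] <- C
    temp_out[r, ] <- tb
    tou <- eng$r_o2p * (C[, TR_PO4] - C[, TR_PRE])
    gl[r, ] <- c(sum(V * C[, TR_O2]) * PMOL_PER_MMOL,
                 sum(V * C[, TR_NO3]) * PMOL_PER_MMOL,
                 sum(V * C[, TR_PO4]) * PMOL_PER_MMOL,
                 sum(V * C[, TR_ABIO]) * PMOL_PER_MMOL,
                 sum(V * tou) * PMOL_PER_MMOL,
                 sum(V * C[, TR_PRE]) * PMOL_PER_MMOL,
                 acc$airsea * PMOL_PER_MMOL,
                 acc$airsea_abio * PMOL_PER_MMOL,
                 acc$fixation_n * PMOL_PER_MMOL,
                 acc$denit_n * PMOL_PER_MMOL,
                 (acc$fixation_n - prev[1]) / out_every * 1e-15,  # Tmol N yr^-1
                 (acc$denit_n - prev[2]) / out_every * 1e-15,
                 (acc$ncp_p - prev[3]) / out_every * 1e-15,       # Tmol P yr^-1
                 sum(V[C[, TR_O2] < eng$thr]),
                 sum(V * C[, TR_AGE]) / sum(V),
                 frc$psi[step])
  }
  if (acc$remainder_p > 0.01 * max(acc$ncp_p, 1e-300))
    stop("unremineralised remainder exceeded 1% of export: ",
         "nitrate exhaustion is systematic, not occasional")
  if (acc$clipped != 0)
    warning(sprintf("negative concentrations clipped (total %.3g mmol)",
                    acc$clipped))
  globals <- data.frame(time = t0 + seq_len(nout) * out_every, gl)
  structure(list(times = globals$time, conc = conc_out, temp = temp_out,
                 globals = globals,
                 final_state = structure(list(time = t0 + nsteps * dt,
                                              conc = C,
                                              temp = eng$temp0 + frc$Ta[nsteps, ]),
                                         class = "ox_state"),
                 fluxes = as.list(acc), config = config),
            class = "ox_run")
}

#' Spin the model up to a pre-industrial steady state
#'
#' Integrates under constant pre-industrial forcing until the model is
#' steady, first at a coarse step for the bulk of the adjustment and then
#' at the configured `dt` to polish. Because the hard suboxic switch pins
#' the OMZ box in a thin flicker band around the oxygen threshold (width of
#' order the per-step consumption), the steady state is statistical, and
#' convergence is measured on chunk-averaged states: the maximum relative
#' change per year between consecutive `check_every`-year mean states must
#' fall below `tol`. Errors (carrying the residual) if `max_years` is
#' reached without convergence. Starting from an already spun-up state,
#' the first check passes immediately.
#'
#' @param config an [ox_config()].
#' @param tol convergence tolerance, relative change of the chunk-mean
#'   state per year (default from the config).
#' @param max_years cap on total spin-up length (default from the config).
#' @param check_every chunk length between convergence checks, yr.
#' @param state optional starting `ox_state` (default: [init_state()]).
#' @param quiet suppress progress messages.
#' @return converged `ox_state` with attribute `"convergence"` (list:
#'   `years`, `residual`, `tol`, `converged`).
#' @export
spinup <- function(config, tol = config$integration$spinup_tol,
                   max_years = config$integration$spinup_max_years,
                   check_every = 500, state = init_state(config),
                   quiet = TRUE) {
  eng <- compile_engine(config)
  C <- state$conc
  acc <- new_acc()
  total <- 0
  resid <- Inf
  # probe at the final step size first: a state that is already spun up
  # (e.g. re-entering the converged state) exits after two check chunks
  # without the coarse phase disturbing it
  probe_dt <- config$integration$dt
  nchunk <- max(1L, round(check_every / probe_dt))
  Mold <- NULL
  for (chunk in 1:2) {
    Msum <- C * 0
    for (k in seq_len(nchunk)) {
      C <- step_core(C, eng$temp0, 1, eng, probe_dt, acc)
      Msum <- Msum + C
    }
    Mnew <- Msum / nchunk
    total <- total + nchunk * probe_dt
    if (!is.null(Mold))
      resid <- max(abs(Mnew - Mold) / (abs(Mnew) + 1e-2)) / (nchunk * probe_dt)
    Mold <- Mnew
  }
  if (resid < tol) {
    st <- structure(list(time = 0, conc = C, temp = eng$temp0),
                    class = "ox_state")
    attr(st, "convergence") <- list(years = total, residual = resid,
                                    tol = tol, converged = TRUE)
    return(st)
  }
  coarse_tol <- max(tol, 1e-4)  # the coarse step only roughs in the state
  phases <- list(list(dt = config$integration$spinup_coarse_dt,
                      budget = 0.8 * max_years, tol = coarse_tol),
                 list(dt = config$integration$dt,
                      budget = 0.2 * max_years, tol = tol))
  for (ph in phases) {
    dt <- ph$dt
    nchunk <- max(1L, round(check_every / dt))
    used <- 0
    Mold <- NULL
    repeat {
      Msum <- C * 0
      for (k in seq_len(nchunk)) {
        C <- step_core(C, eng$temp0, 1, eng, dt, acc)
        Msum <- Msum + C
      }
      Mnew <- Msum / nchunk
      used <- used + nchunk * dt
      total <- total + nchunk * dt
      if (!is.null(Mold))
        resid <- max(abs(Mnew - Mold) / (abs(Mnew) + 1e-2)) / (nchunk * dt)
      Mold <- Mnew
      if (!quiet) message(sprintf("spin-up t=%.0f dt=%.2f residual=%.3g",
                                  total, dt, resid))
      if (any(!is.finite(C))) stop("NaN during spin-up at year ", total)
      if (resid < ph$tol || used >= ph$budget) break
    }
  }
  if (resid >= tol)
    stop(sprintf("spin-up did not converge within %g years (residual %.3g, tol %.3g)",
                 max_years, resid, tol))
  st <- structure(list(time = 0, conc = C, temp = eng$temp0), class = "ox_state")
  attr(st, "convergence") <- list(years = total, residual = resid, tol = tol,
                                  converged = TRUE)
  st
}

#' @export
print.ox_state <- function(x, ...) {
  cat(sprintf("ocean state at t = %.2f yr\n", x$time))
  print(round(cbind(x$conc, temp = x$temp), 3))
  invisible(x)
}

#' @export
print.ox_run <- function(x, ...) {
  g <- x$globals
  cat(sprintf("oxybox run: %d outputs, years %.0f-%.0f\n",
              nrow(g), min(g$time), max(g$time)))
  cat(sprintf("  O2 inventory %.2f -> %.2f Pmol; NO3 %.2f -> %.2f Pmol\n",
              g$o2_inv[1], g$o2_inv[nrow(g)], g$no3_inv[1], g$no3_inv[nrow(g)]))
  cat(sprintf("  cumulative air-sea O2 flux %.2f Pmol; fixation %.3f, denitrification %.3f Pmol N\n",
              g$cum_airsea[nrow(g)], g$cum_fixation[nrow(g)], g$cum_denit[nrow(g)]))
  invisible(x)
}
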