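#' Decompose the oxygen-inventory change over a time window
#'
#' The headline accounting: between `t0` and `t1`, the oxygen-inventory
#' change is split into the cumulative air-sea flux and the oxygen
#' equivalent of the net nitrate-inventory loss, and cross-checked against
#' the tracer pair (abiotic O2 for solubility, minus TOU for the stored
#' respiratory deficit). Two closure residuals are reported: the primary
#' identity
#' `dO2 - cumulative flux - o2_equivalent(-dNO3)` (zero up to integration
#' error and the unremineralised remainder) and the flux identity
#' `cumulative flux - (dAbiotic + d(-TOU))` (zero up to surface
#' disequilibrium; exact in the infinite-piston-velocity limit).
#'
#' @param run an `ox_run` from [run_simulation()].
#' @param t0,t1 window bounds in run years (must be covered by the run;
#'   `t1 > t0` except that `t0 == t1` yields an all-zero decomposition).
#' @param stoich an [stoich_params()]; defaults to the run's.
#' @return An `ox_budget` list, all in Pmol: `window`, `d_o2`, `d_abiotic`,
#'   `d_tou`, `airsea_flux`, `d_no3`, `no3_loss_o2_equiv`,
#'   `residual_primary`, `residual_flux_tracers`.
#' @export
decompose_budget <- function(run, t0 = min(run$times), t1 = max(run$times),
                             stoich = run$config$stoich) {
  if (t1 < t0) stop("reversed window: t1 must not precede t0")
  g <- run$globals
  if (t0 < min(g$time) || t1 > max(g$time))
    stop("window outside the run output range")
  at <- function(col, t) stats::approx(g$time, g[[col]], t)$y
  d <- function(col) at(col, t1) - at(col, t0)
  d_no3 <- d("no3_inv")
  flux <- d("cum_airsea")
  d_o2 <- d("o2_inv")
  d_ab <- d("abio_inv")
  d_tou <- d("tou_inv")
  equiv <- o2_equivalent_of_nitrate_loss(-d_no3, stoich)
  structure(list(window = c(t0 = t0, t1 = t1),
                 d_o2 = d_o2, d_abiotic = d_ab, d_tou = d_tou,
                 airsea_flux = flux, d_no3 = d_no3,
                 no3_loss_o2_equiv = equiv,
                 residual_primary = d_o2 - flux - equiv,
                 residual_flux_tracers = flux - (d_ab - d_tou)),
            class = "ox_budget")
}

#' @export
print.ox_budget <- function(x, ...) {
  cat(sprintf("oxygen budget, years %.0f-%.0f (Pmol O2)\n",
              x$window[1], x$window[2]))
  cat(sprintf("  dO2 inventory        %+8.3f\n", x$d_o2))
  cat(sprintf("  air-sea flux         %+8.3f\n", x$airsea_flux))
  cat(sprintf("  nitrate-loss equiv.  %+8.3f  (dNO3 = %+.3f Pmol)\n",
              x$no3_loss_o2_equiv, x$d_no3))
  cat(sprintf("  abiotic / -TOU       %+8.3f / %+8.3f\n", x$d_abiotic, -x$d_tou))
  cat(sprintf("  residual (primary)   %+8.2e\n", x$residual_primary))
  cat(sprintf("  residual (flux-trc)  %+8.2e\n", x$residual_flux_tracers))
  invisible(x)
}

#' Suboxic volume of a state
#'
#' Total volume of boxes with dissolved oxygen strictly below the suboxic
#' threshold (5 mmol m^-3 by default; a box at exactly the threshold is
#' oxic -- the switch is "below").
#'
#' @param state an `ox_state`.
#' @param stoich an [stoich_params()] (for the threshold).
#' @param geometry the matching [box_geometry()].
#' @return suboxic volume in m^3.
#' @export
suboxic_volume <- function(state, stoich = stoich_params(),
                           geometry = box_geometry()) {
  sum(geometry$volumes[state$conc[, TR_O2] < stoich$o2_threshold])
}

#' Onset of a sustained rise in a rate series
#'
#' First time at which the series exceeds its control mean plus `k`
#' control standard deviations for at least `m` consecutive years. Two
#' robustifications matter in practice: the threshold never sits closer to
#' the control mean than `rel_floor` times its magnitude (the suboxic
#' switch can make a control series either essentially noise-free or
#' strongly flickering, and a vanishing control variance would otherwise
#' flag any infinitesimal drift), and callers are expected to smooth
#' flickering series first (see [detect_lag()]).
#'
#' @param times sample times, yr.
#' @param series the rate series.
#' @param control_mean,control_sd statistics of the undisturbed series
#'   (e.g. over a control run or the last centuries of the spin-up).
#' @param k threshold in control standard deviations (default 2).
#' @param m required consecutive exceedance, yr (default 10).
#' @param rel_floor minimum threshold offset as a fraction of the control
#'   mean (default 0.05).
#' @return onset time in yr, or `NA` if no sustained rise is found.
#' @export
onset_time <- function(times, series, control_mean, control_sd, k = 2, m = 10,
                       rel_floor = 0.05) {
  thr <- control_mean + max(k * max(control_sd, 0),
                            rel_floor * abs(control_mean))
  over <- series > thr
  if (!any(over)) return(NA_real_)
  dt_s <- if (length(times) > 1) stats::median(diff(times)) else 1
  need <- max(1L, ceiling(m / dt_s))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  times[starts[ok[1]]]
}

# centred running mean with shrinking windows at the edges, so a pure time
# shift of a series shifts its smoothed version identically
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Lag of the nitrogen-fixation response behind denitrification
#'
#' Onset of the sustained rise of each series ([onset_time()]); returns the
#' fixation onset minus the denitrification onset. Both series (and the
#' control series, if given as series) are smoothed with a centred
#' `smooth_years` running mean first, because denitrification in a
#' threshold box model is bursty at annual resolution. Identical series
#' give 0 and a pure time shift returns that shift; in the warming
#' experiment the fixation response lags because the nitrogen deficit must
#' first be upwelled to warm, fixation-capable surface waters.
#'
#' @param times sample times, yr.
#' @param denit_series,fix_series denitrification and fixation rate series.
#' @param control a list with `denit = c(mean, sd)` and `fix = c(mean, sd)`
#'   control statistics (computed from equally smoothed control series), or
#'   `NULL` to estimate both from the first `control_years` of the series.
#' @param control_years initial window used when `control` is `NULL`, yr.
#' @param k,m,rel_floor onset-detection parameters, see [onset_time()].
#' @param smooth_years running-mean window, yr (default 21; 1 disables).
#' @return list with `lag` (yr; `NA` if either onset is undefined),
#'   `onset_denit`, `onset_fix`.
#' @export
detect_lag <- function(times, denit_series, fix_series, control = NULL,
                       control_years = 100, k = 2, m = 10, rel_floor = 0.05,
                       smooth_years = 21) {
  dt_s <- if (length(times) > 1) stats::median(diff(times)) else 1
  w <- max(1L, round(smooth_years / dt_s))
  den <- running_mean(denit_series, w)
  fix <- running_mean(fix_series, w)
  if (is.null(control)) {
    in_w <- times <= times[1] + control_years
    control <- list(denit = c(mean(den[in_w]), stats::sd(den[in_w])),
                    fix = c(mean(fix[in_w]), stats::sd(fix[in_w])))
  }
  od <- onset_time(times, den, control$denit[1], control$denit[2], k, m, rel_floor)
  of <- onset_time(times, fix, control$fix[1], control$fix[2], k, m, rel_floor)
  list(lag = of - od, onset_denit = od, onset_fix = of)
}

#' Qualitative run report
#'
#' Summarises a (typically warming) run against an optional control run:
#' the oxygen trajectory (transient decline, final overshoot), the nitrate
#' inventory change, the NCP dip and recovery, suboxic-volume expansion,
#' the fixation/denitrification lag, the deep N* change, and the full
#' budget decomposition over the run.
#'
#' @param run an `ox_run`.
#' @param control optional control `ox_run` used for onset statistics and
#'   the suboxic-volume baseline (otherwise the run's first
#'   `control_years` serve as baseline).
#' @param control_years baseline window, yr.
#' @return An `ox_report` list; see the fields in the implementation, all
#'   plain numbers/logicals plus the `ox_budget`.
#' @export
report <- function(run, control = NULL, control_years = 100) {
  g <- run$globals
  base <- if (!is.null(control)) control$globals else
    g[g$time <= g$time[1] + control_years, ]
  sm_den <- running_mean(base$denit_rate, 21)
  sm_fix <- running_mean(base$fixation_rate, 21)
  ctrl <- list(denit = c(mean(sm_den), stats::sd(sm_den)),
               fix = c(mean(sm_fix), stats::sd(sm_fix)))
  lag <- detect_lag(g$time, g$denit_rate, g$fixation_rate, control = ctrl)
  n <- nrow(g)
  dz <- match("Deep", rownames(run$conc[1, , ]))
  nstar0 <- nstar(run$conc[1, dz, TR_NO3], run$conc[1, dz, TR_PO4])
  nstar1 <- nstar(run$conc[n, dz, TR_NO3], run$conc[n, dz, TR_PO4])
  structure(list(
    budget = decompose_budget(run),
    o2_initial = g$o2_inv[1], o2_min = min(g$o2_inv), o2_final = g$o2_inv[n],
    o2_transient_decline = min(g$o2_inv) < g$o2_inv[1],
    o2_final_overshoot = g$o2_inv[n] > g$o2_inv[1],
    no3_initial = g$no3_inv[1], no3_final = g$no3_inv[n],
    no3_net_loss = g$no3_inv[1] - g$no3_inv[n],
    ncp_initial = mean(g$ncp_rate[seq_len(min(50, n))]),
    ncp_min = min(g$ncp_rate), ncp_final = mean(g$ncp_rate[max(1, n - 49):n]),
    suboxic_mean = mean(g$suboxic_vol),
    suboxic_max = max(g$suboxic_vol),
    suboxic_baseline = mean(base$suboxic_vol),
    lag = lag$lag, onset_denit = lag$onset_denit, onset_fix = lag$onset_fix,
    deep_nstar_initial = nstar0, deep_nstar_final = nstar1,
    flat = (max(g$o2_inv) - min(g$o2_inv)) < 0.05 &&
      (max(g$no3_inv) - min(g$no3_inv)) < 0.05),
    class = "ox_report")
}

#' @export
print.ox_report <- function(x, ...) {
  cat("run report\n")
  cat(sprintf("  O2 inventory: %.2f -> min %.2f -> final %.2f Pmol (decline %s, overshoot %s)\n",
              x$o2_initial, x$o2_min, x$o2_final,
              x$o2_transient_decline, x$o2_final_overshoot))
  cat(sprintf("  NO3 inventory: %.2f -> %.2f Pmol (net loss %.2f)\n",
              x$no3_initial, x$no3_final, x$no3_net_loss))
  cat(sprintf("  NCP (Tmol P/yr): start %.3f, min %.3f, final %.3f\n",
              x$ncp_initial, x$ncp_min, x$ncp_final))
  cat(sprintf("  suboxic volume: baseline %.3g, mean %.3g, max %.3g m^3\n",
              x$suboxic_baseline, x$suboxic_mean, x$suboxic_max))
  cat(sprintf("  fixation lag behind denitrification: %s yr\n",
              format(x$lag)))
  cat(sprintf("  deep N*: %.2f -> %.2f mmol m^-3\n",
              x$deep_nstar_initial, x$deep_nstar_final))
  print(x$budget)
  invisible(x)
}
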