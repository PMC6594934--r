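#' Scenario parameters for the prescribed warming experiment
#'
#' The multi-millennial experiment is driven by prescribed trajectories of
#' per-box temperature anomaly and of a dimensionless overturning scale
#' factor; emissions, atmospheric CO2 and the climate response are not
#' modelled. Anchor points: volume-weighted mean ocean warming reaches
#' `d_t_ocean` (default 3.1 degC) exactly at `t_peak` (default year 3380);
#' the overturning first weakens (minimum before year 2500), recovers with
#' a maximum near year 3080 and levels off slightly above pre-industrial.
#'
#' @param year_start,year_end time span of the forcing, yr.
#' @param d_t_ocean peak volume-weighted mean ocean warming, degC.
#' @param t_peak year at which the volume-weighted anomaly equals
#'   `d_t_ocean`.
#' @param warming_pattern named per-box relative warming amplitudes
#'   (surface boxes warm more than the deep); rescaled internally so the
#'   volume-weighted constraint holds exactly.
#' @param warming_mid,warming_tau named per-box logistic midpoints and
#'   widths, yr (deep boxes lag the surface).
#' @param moc_dip_depth,moc_dip_year,moc_dip_width Gaussian overturning
#'   reduction (dimensionless depth, centre yr, width yr).
#' @param moc_bump_height,moc_bump_year,moc_bump_width Gaussian recovery
#'   overshoot centred near the post-recovery maximum.
#' @param moc_final final overturning factor (slightly above 1).
#' @param noise_sd standard deviation of optional white forcing noise
#'   (default 0: the scenario is deterministic); `seed` is used only if
#'   this is positive.
#' @return An `ox_scenario_params` list.
#' @export
scenario_params <- function(year_start = 1850, year_end = 8000,
                            d_t_ocean = 3.1, t_peak = 3380,
                            warming_pattern = c(LowLatSurface = 1.45,
                                                SouthernOceanSurface = 0.95,
                                                NorthSurface = 1.30,
                                                OMZ = 1.10,
                                                Thermocline = 1.15,
                                                Deep = 0.97),
                            warming_mid = c(LowLatSurface = 2150,
                                            SouthernOceanSurface = 2300,
                                            NorthSurface = 2150,
                                            OMZ = 2450,
                                            Thermocline = 2350,
                                            Deep = 2800),
                            warming_tau = c(LowLatSurface = 90,
                                            SouthernOceanSurface = 120,
                                            NorthSurface = 90,
                                            OMZ = 160,
                                            Thermocline = 140,
                                            Deep = 180),
                            moc_dip_depth = 0.40, moc_dip_year = 2150,
                            moc_dip_width = 180,
                            moc_bump_height = 0.12, moc_bump_year = 3080,
                            moc_bump_width = 500,
                            moc_final = 1.05,
                            noise_sd = 0) {
  p <- as.list(environment())
  class(p) <- "ox_scenario_params"
  if (year_end <= year_start) stop("scenario must end after it starts")
  if (t_peak <= year_start || t_peak > year_end)
    stop("inconsistent timing: warming peak outside the scenario span")
  if (moc_dip_depth >= 1) stop("overturning factor must stay positive")
  p
}

logistic01 <- function(t, mid, tau) 1 / (1 + exp(-(t - mid) / tau))

#' Generate the prescribed warming-scenario forcing
#'
#' Per-box temperature anomalies follow lagged logistics (zero at the start
#' year by construction, surface boxes leading the deep), rescaled by a
#' single factor so the volume-weighted mean anomaly at the peak year
#' equals `d_t_ocean` to machine precision. The overturning factor is a
#' dip-recovery-overshoot curve that stays positive and ends slightly
#' above 1.
#'
#' @param params an [scenario_params()] object.
#' @param geometry an [box_geometry()] object (for volume weights and box
#'   labels).
#' @param seed integer; consumed only when `noise_sd > 0`.
#' @return An `ox_forcing` list: `years`, `temp_anomaly` (years x boxes
#'   matrix, degC), `psi_factor` (vector), and the generating `params`.
#' @export
make_warming_scenario <- function(params = scenario_params(),
                                  geometry = box_geometry(), seed = 1L) {
  yrs <- seq(params$year_start, params$year_end, by = 1)
  lbl <- geometry$labels
  need <- function(x, what) {
    if (!all(lbl %in% names(x)))
      stop("scenario ", what, " missing boxes: ",
           paste(setdiff(lbl, names(x)), collapse = ", "))
    x[lbl]
  }
  pat <- need(params$warming_pattern, "warming_pattern")
  mid <- need(params$warming_mid, "warming_mid")
  tau <- need(params$warming_tau, "warming_tau")

  shape <- sapply(seq_along(lbl), function(b) {
    s0 <- logistic01(params$year_start, mid[b], tau[b])
    (logistic01(yrs, mid[b], tau[b]) - s0) / (1 - s0)
  })
  colnames(shape) <- lbl
  w <- geometry$volumes / sum(geometry$volumes)
  if (params$d_t_ocean == 0) {
    anom <- shape * 0
  } else {
    at_peak <- shape[match(params$t_peak, yrs), ]
    denom <- sum(w * pat * at_peak)
    if (denom <= 0) stop("inconsistent timing: no warming reaches the peak year")
    anom <- sweep(shape, 2, pat * (params$d_t_ocean / denom), `*`)
  }

  gauss <- function(t, mid, wdt) exp(-((t - mid) / wdt)^2)
  psi <- 1 -
    params$moc_dip_depth * gauss(yrs, params$moc_dip_year, params$moc_dip_width) +
    params$moc_bump_height * gauss(yrs, params$moc_bump_year, params$moc_bump_width) +
    (params$moc_final - 1) * logistic01(yrs, params$moc_bump_year - 280, 200)
  if (params$d_t_ocean == 0) psi <- rep(1, length(yrs))
  if (any(psi <= 0)) stop("overturning factor must stay positive")

  if (params$noise_sd > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    anom <- anom + matrix(stats::rnorm(length(anom), 0, params$noise_sd),
                          nrow = nrow(anom))
  }
  structure(list(years = yrs, temp_anomaly = anom, psi_factor = psi,
                 params = params),
            class = "ox_forcing")
}

#' Pre-industrial control forcing
#'
#' Zero temperature anomalies and unit overturning factor.
#'
#' @param years year grid (default 1850-8000) or a single count of years.
#' @param geometry an [box_geometry()] object.
#' @return An `ox_forcing` list.
#' @export
make_control_scenario <- function(years = seq(1850, 8000), geometry = box_geometry()) {
  if (length(years) == 1) years <- seq(1850, 1850 + years - 1)
  anom <- matrix(0, length(years), geometry$n_boxes,
                 dimnames = list(NULL, geometry$labels))
  structure(list(years = years, temp_anomaly = anom,
                 psi_factor = rep(1, length(years)),
                 params = NULL),
            class = "ox_forcing")
}

#' Write / read forcing as CSV
#'
#' One row per year: `year`, one temperature-anomaly column per box
#' (`dT_<box>`, degC), and `psi_factor`, so externally produced
#' trajectories can be swapped in.
#'
#' @param forcing an `ox_forcing` object.
#' @param path CSV file path.
#' @return `write_forcing_csv` returns `path` invisibly;
#'   `read_forcing_csv` returns an `ox_forcing`.
#' @export
write_forcing_csv <- function(forcing, path) {
  df <- data.frame(year = forcing$years,
                   forcing$temp_anomaly,
                   psi_factor = forcing$psi_factor,
                   check.names = FALSE)
  names(df)[2:(1 + ncol(forcing$temp_anomaly))] <-
    paste0("dT_", colnames(forcing$temp_anomaly))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^dT_", names(df), value = TRUE)
  anom <- as.matrix(df[tcols])
  colnames(anom) <- sub("^dT_", "", tcols)
  structure(list(years = df$year, temp_anomaly = anom,
                 psi_factor = df$psi_factor, params = NULL),
            class = "ox_forcing")
}
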