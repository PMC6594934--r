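#' Write / read a model configuration as YAML
#'
#' The full configuration (geometry, circulation, stoichiometry, ecosystem,
#' gas exchange, integration, initial conditions) round-trips through a
#' single structured YAML file; [default_config_yaml()] dumps the package
#' defaults so they can be edited.
#'
#' @param config an [ox_config()].
#' @param path YAML file path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   a validated `ox_config`.
#' @export
write_config_yaml <- function(config, path) {
  g <- config$geometry
  x <- list(
    geometry = list(volumes = as.list(stats::setNames(g$volumes, g$labels)),
                    surface_areas = as.list(stats::setNames(
                      g$surface_areas[g$is_surface], g$labels[g$is_surface])),
                    temperatures = as.list(stats::setNames(g$temperatures,
                                                           g$labels))),
    circulation = list(psi = config$circulation$psi,
                       loop = config$circulation$loop,
                       mixing = config$circulation$mixing),
    stoichiometry = unclass(config$stoich),
    ecosystem = lapply(unclass(config$ecosystem), function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else
        if (is.list(v)) lapply(v, as.list) else v),
    gas_exchange = unclass(config$gasex),
    integration = config$integration,
    init = lapply(config$init, function(v) if (is.null(v)) NULL else as.numeric(v)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  unl <- function(l) unlist(l)
  geo <- box_geometry(volumes = unl(x$geometry$volumes),
                      surface_areas = unl(x$geometry$surface_areas),
                      temperatures = unl(x$geometry$temperatures))
  eco <- x$ecosystem
  ox_config(
    geometry = geo,
    circulation = circulation_scheme(psi = x$circulation$psi,
                                     loop = unlist(x$circulation$loop),
                                     mixing = x$circulation$mixing),
    stoich = do.call(stoich_params, x$stoichiometry),
    ecosystem = ecosystem_params(
      mu_max_phy = eco$mu_max_phy, mu_max_diaz = eco$mu_max_diaz,
      k_no3 = eco$k_no3, k_po4 = eco$k_po4, k_po4_diaz = eco$k_po4_diaz,
      temp_cutoff_diaz = eco$temp_cutoff_diaz,
      biomass_proxy = eco$biomass_proxy, export_frac = eco$export_frac,
      prod_scale = unl(eco$prod_scale),
      remin_partition = lapply(eco$remin_partition, unl),
      remin_t_sens = eco$remin_t_sens,
      fixation_enabled = eco$fixation_enabled,
      denitrification_enabled = eco$denitrification_enabled),
    gasex = do.call(gasex_params, x$gas_exchange),
    dt = x$integration$dt, output_every = x$integration$output_every,
    spinup_tol = x$integration$spinup_tol,
    spinup_max_years = x$integration$spinup_max_years,
    spinup_coarse_dt = x$integration$spinup_coarse_dt,
    budget_tol = x$integration$budget_tol,
    init = x$init)
}

#' @rdname write_config_yaml
#' @export
default_config_yaml <- function(path) write_config_yaml(ox_config(), path)

#' Write run output as CSV
#'
#' One row per output interval: the global diagnostics (inventories in
#' Pmol, cumulative fluxes in Pmol, interval-mean rates in Tmol yr^-1,
#' suboxic volume in m^3) followed by one column per box-tracer in
#' mmol m^-3 (age in yr) and per-box temperature in degC. Units are
#' annotated in the header names.
#'
#' @param run an `ox_run`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  g <- run$globals
  units <- c(time = "yr", o2_inv = "Pmol", no3_inv = "Pmol", po4_inv = "Pmol",
             abio_inv = "Pmol", tou_inv = "Pmol", pre_inv = "Pmol",
             cum_airsea = "Pmol", cum_airsea_abio = "Pmol",
             cum_fixation = "Pmol", cum_denit = "Pmol",
             fixation_rate = "TmolN.yr", denit_rate = "TmolN.yr",
             ncp_rate = "TmolP.yr", suboxic_vol = "m3", mean_age = "yr",
             psi_factor = "1")
  names(g) <- paste0(names(g), ".", units[names(g)])
  boxes <- dimnames(run$conc)[[2]]
  tr <- dimnames(run$conc)[[3]]
  wide <- do.call(cbind, lapply(seq_along(tr), function(j) {
    m <- run$conc[, , j, drop = FALSE]
    dim(m) <- dim(run$conc)[1:2]
    colnames(m) <- paste0(tr[j], ".", boxes,
                          if (tr[j] == "age") ".yr" else ".mmol.m3")
    m
  }))
  tempm <- run$temp
  colnames(tempm) <- paste0("temp.", boxes, ".degC")
  utils::write.csv(cbind(g, wide, tempm), path, row.names = FALSE)
  invisible(path)
}

#' Write a state snapshot as CSV
#'
#' @param state an `ox_state`.
#' @param path CSV file path.
#' @return `path` invisibly; `read_state_csv` returns the `ox_state`.
#' @export
write_state_csv <- function(state, path) {
  df <- data.frame(box = rownames(state$conc), state$conc,
                   temp = state$temp, time = state$time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path)
  conc <- as.matrix(df[TRACER_NAMES])
  rownames(conc) <- df$box
  structure(list(time = df$time[1], conc = conc, temp = df$temp),
            class = "ox_state")
}
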