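#' Ecosystem parameters
#'
#' Biology is not prognostic: production follows Monod factors times a
#' maximal growth rate times an implicit biomass proxy, a
#' nutrient-restoring-like closure that reproduces inventory-level nutrient
#' drawdown without carrying plankton state variables. Nitrogen fixers
#' (diazotrophs) grow at less than half the ordinary maximal rate, not at
#' all below a hard temperature cutoff, and are never limited by fixed
#' nitrogen; they compete with ordinary phytoplankton only through
#' phosphate.
#'
#' @param mu_max_phy maximal specific growth rate of ordinary phytoplankton,
#'   yr^-1.
#' @param mu_max_diaz maximal diazotroph rate, yr^-1; must be below
#'   `0.5 * mu_max_phy`.
#' @param k_no3,k_po4 half-saturation constants of ordinary phytoplankton,
#'   mmol m^-3 (Redfield-consistent 16:1 by default).
#' @param k_po4_diaz diazotroph phosphate half-saturation, mmol m^-3
#'   (larger than `k_po4`: diazotrophs are poorer phosphate competitors).
#' @param temp_cutoff_diaz diazotroph growth is zero strictly below this
#'   temperature, degrees C (hard step, not a ramp).
#' @param biomass_proxy implicit standing biomass, mmol P m^-3.
#' @param export_frac fraction of net production exported from each surface
#'   box (the remainder is recycled in place with no net tracer effect).
#' @param prod_scale named per-surface-box production efficiency in [0, 1],
#'   standing in for the light/micronutrient limitations the box model does
#'   not resolve (low in the Southern Ocean).
#' @param remin_partition named list: for each surface box, a named vector
#'   of fractions (summing to 1) routing its export to interior boxes.
#' @param remin_t_sens shift of the low-latitude export partition toward the
#'   shallowest interior box (Thermocline if present, else OMZ) per degree
#'   of local surface warming -- faster and hence shallower
#'   remineralisation in a warmer ocean -- in 1/degC. Set to 0 to disable.
#' @param fixation_enabled,denitrification_enabled master switches used by
#'   counterfactual experiments.
#' @param fixation_compensating if `TRUE`, nitrogen fixation compensates
#'   denitrification instantaneously: on top of the prognostic diazotrophs,
#'   any step-level imbalance between the net nitrate removal by
#'   denitrification and prognostic fixation is topped up in the warmest
#'   surface box, at the oxygen cost of `o2_per_no3_lost()` per mole N.
#'   The fixed-nitrogen inventory is then exactly conserved. See
#'   [instant_fixation_config()].
#' @return An `ox_ecosystem` parameter list.
#' @export
ecosystem_params <- function(mu_max_phy = 40,
                             mu_max_diaz = 18,
                             k_no3 = 1.6,
                             k_po4 = 0.1,
                             k_po4_diaz = 2.5,
                             temp_cutoff_diaz = 15,
                             biomass_proxy = 0.004,
                             export_frac = 0.9,
                             prod_scale = c(LowLatSurface = 1.0,
                                            SouthernOceanSurface = 0.15,
                                            NorthSurface = 0.5),
                             remin_partition = list(
                               LowLatSurface = c(OMZ = 0.22, Thermocline = 0.45,
                                                 Deep = 0.33),
                               SouthernOceanSurface = c(Deep = 1),
                               NorthSurface = c(Deep = 1)),
                             remin_t_sens = 0.015,
                             fixation_enabled = TRUE,
                             denitrification_enabled = TRUE,
                             fixation_compensating = FALSE) {
  p <- list(mu_max_phy = mu_max_phy, mu_max_diaz = mu_max_diaz,
            k_no3 = k_no3, k_po4 = k_po4, k_po4_diaz = k_po4_diaz,
            temp_cutoff_diaz = temp_cutoff_diaz,
            biomass_proxy = biomass_proxy, export_frac = export_frac,
            prod_scale = prod_scale, remin_partition = remin_partition,
            remin_t_sens = remin_t_sens,
            fixation_enabled = fixation_enabled,
            denitrification_enabled = denitrification_enabled,
            fixation_compensating = fixation_compensating)
  class(p) <- "ox_ecosystem"
  validate_ecosystem(p)
  p
}

validate_ecosystem <- function(p) {
  if (p$mu_max_diaz >= 0.5 * p$mu_max_phy)
    stop("diazotroph maximal growth rate must be less than half the ordinary one")
  if (any(c(p$mu_max_phy, p$k_no3, p$k_po4, p$k_po4_diaz,
            p$biomass_proxy) <= 0) || p$mu_max_diaz < 0)
    stop("ecosystem rates and half-saturations must be positive")
  if (p$export_frac < 0 || p$export_frac > 1)
    stop("export fraction must lie in [0, 1]")
  for (frac in p$remin_partition) {
    if (abs(sum(frac) - 1) > 1e-12)
      stop("remineralisation partition fractions must sum to 1")
    if (any(frac < 0)) stop("remineralisation partition fractions must be non-negative")
  }
  invisible(p)
}

#' Ordinary (nitrate-using) phytoplankton production
#'
#' Liebig minimum of the nitrate and phosphate Monod factors times the
#' maximal rate and the implicit biomass; returns a volumetric rate.
#' Zero whenever either nutrient is exhausted.
#'
#' @param no3,po4 surface concentrations, mmol m^-3.
#' @param temp surface temperature, degrees C (unused by the ordinary
#'   class; kept for a uniform signature).
#' @param params an [ecosystem_params()] object.
#' @param scale production efficiency of the box (see `prod_scale`).
#' @return production rate in mmol P m^-3 yr^-1.
#' @export
ordinary_production <- function(no3, po4, temp, params, scale = 1) {
  lim <- pmin(no3 / (params$k_no3 + no3), po4 / (params$k_po4 + po4))
  pmax(0, params$mu_max_phy * lim * params$biomass_proxy * scale)
}

#' Diazotroph production
#'
#' Phosphate-Monod growth of nitrogen fixers: zero strictly below the
#' temperature cutoff, never limited by fixed nitrogen. Each mol P of
#' diazotroph production fixes `r_np` mol of new nitrogen.
#'
#' @inheritParams ordinary_production
#' @return production rate in mmol P m^-3 yr^-1.
#' @export
diazotroph_production <- function(po4, temp, params, scale = 1) {
  if (!params$fixation_enabled) return(po4 * 0)
  on <- as.numeric(temp >= params$temp_cutoff_diaz)
  pmax(0, params$mu_max_diaz * po4 / (params$k_po4_diaz + po4) *
         params$biomass_proxy * scale * on)
}

#' Remineralise an organic-phosphorus flux against available oxidants
#'
#' At or above the suboxic threshold the pathway is aerobic: `r_o2p` mol O2
#' consumed and `r_np` mol NO3 regenerated per mol P. Strictly below the
#' threshold nitrate is the electron acceptor: `r_no3p` mol NO3 consumed
#' per mol P with the organic nitrogen returned to the fixed pool, so the
#' nitrate tracer loses `r_no3p - r_np` per mol P at this step and no
#' oxygen is consumed. When nitrate is exhausted remineralisation stops and
#' the remainder is reported.
#'
#' With `vol` and `dt` supplied, the pathway split is additionally limited
#' by what the box holds: aerobic consumption cannot drive O2 negative
#' within the step and denitrification cannot drive NO3 negative; the
#' aerobic/anaerobic decision itself is made on the concentration at the
#' start of the step (at exactly the threshold the pathway is aerobic).
#' Without them the split is the pure threshold rule.
#'
#' @param org_p_flux organic phosphorus supply, mmol P yr^-1 (must be >= 0).
#' @param o2,no3 ambient concentrations, mmol m^-3.
#' @param stoich an [stoich_params()] object.
#' @param vol box volume, m^3 (optional, see Details).
#' @param dt time step, yr (optional).
#' @return list with rates in mmol yr^-1: `d_o2`, `d_no3`, `d_po4` (net
#'   tracer tendencies), `denit_no3` (gross nitrate consumed as electron
#'   acceptor, `r_no3p` per denitrified P -- the quantity reported as the
#'   denitrification rate), `denit_frac` (fraction of the flux
#'   denitrified, in [0, 1]), and `remainder` (unremineralised organic P,
#'   mmol P yr^-1).
#' @export
remineralize <- function(org_p_flux, o2, no3, stoich, vol = NULL, dt = NULL) {
  if (org_p_flux < 0) stop("organic flux must be non-negative")
  capped <- !is.null(vol) && !is.null(dt)
  aerobic_ok <- o2 >= stoich$o2_threshold
  no3_net <- stoich$r_no3p - stoich$r_np  # net NO3 tracer loss per denitrified P
  if (aerobic_ok) {
    aer <- if (capped) min(org_p_flux, o2 * vol / (stoich$r_o2p * dt)) else org_p_flux
  } else aer <- 0
  rest <- org_p_flux - aer
  if (rest > 0 && no3 > 0) {
    den <- if (capped) min(rest, no3 * vol / (no3_net * dt)) else rest
  } else den <- 0
  remainder <- org_p_flux - aer - den
  list(d_o2 = -stoich$r_o2p * aer,
       d_no3 = stoich$r_np * aer - no3_net * den,
       d_po4 = aer + den,
       denit_no3 = stoich$r_no3p * den,
       denit_frac = if (org_p_flux > 0) den / org_p_flux else 0,
       remainder = remainder)
}

#' Net community production and export of a surface box
#'
#' NCP is the surplus of production over community respiration in the
#' surface box; on the timescales resolved here it equals export. Uptake
#' removes nutrients from the surface box at Redfield ratios for the
#' exported share only (the recycled share has no net tracer effect):
#' ordinary production consumes NO3 and PO4 and releases `r_o2p` mol O2 per
#' mol P; diazotroph production consumes PO4 only, adds `r_np` mol of newly
#' fixed N per mol P to the organic pool, and releases
#' `o2_release_per_p(stoich, diazotroph = TRUE)` mol O2 per mol P. Exported
#' organic matter carries N:P = `r_np` from either class.
#'
#' @param no3,po4 surface concentrations, mmol m^-3.
#' @param temp surface temperature, degrees C.
#' @param vol box volume, m^3.
#' @param params an [ecosystem_params()] object.
#' @param stoich an [stoich_params()] object.
#' @param scale per-box production efficiency.
#' @return list with `export_p` (total exported organic P, mmol yr^-1),
#'   `export_ord`, `export_diaz` (its two components), `fixation_n` (new
#'   fixed N, mmol yr^-1), and net surface tendencies `d_no3`, `d_po4`,
#'   `d_o2` (mmol yr^-1).
#' @export
ncp <- function(no3, po4, temp, vol, params, stoich, scale = 1) {
  ord <- ordinary_production(no3, po4, temp, params, scale) * vol
  diaz <- diazotroph_production(po4, temp, params, scale) * vol
  e_ord <- params$export_frac * ord
  e_diaz <- params$export_frac * diaz
  list(export_p = e_ord + e_diaz,
       export_ord = e_ord,
       export_diaz = e_diaz,
       fixation_n = stoich$r_np * e_diaz,
       d_no3 = -stoich$r_np * e_ord,
       d_po4 = -(e_ord + e_diaz),
       d_o2 = o2_release_per_p(stoich) * e_ord +
         o2_release_per_p(stoich, diazotroph = TRUE) * e_diaz)
}

#' Counterfactual: instantaneously compensating nitrogen fixation
#'
#' Returns a copy of the configuration in which the diazotroph community is
#' effectively unlimited: beyond the prognostic diazotrophs, any step-level
#' imbalance between denitrification's net nitrate removal and prognostic
#' fixation is topped up immediately in the warmest surface box, at the
#' bookkeeping cost of `o2_per_no3_lost()` mol O2 per mol N (the oxygen
#' spent nitrifying the newly fixed nitrogen). The fixed-nitrogen
#' inventory is then exactly conserved, the loophole is closed, and the
#' warming response of the oxygen inventory is flux-only: the comparison
#' run that isolates the fixed-nitrogen-loss oxygen source. Because the
#' compensation term vanishes in the balanced control climate, the default
#' spun-up state serves both runs.
#'
#' @param config an [ox_config()].
#' @return the modified `ox_config`.
#' @export
instant_fixation_config <- function(config) {
  config$ecosystem$fixation_compensating <- TRUE
  validate_config(config)
}
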