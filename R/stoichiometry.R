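#' Stoichiometric parameters of the remineralisation chemistry
#'
#' Fixed elemental ratios of the model's organic matter and the oxidant
#' accounting derived from them. Organic matter has molar C:N:P =
#' `r_cp`:`r_np`:1; its complete aerobic remineralisation (including
#' nitrification of the organic nitrogen back to nitrate) consumes `r_o2p`
#' mol O2 per mol P. Where oxygen falls below `o2_threshold`, nitrate is the
#' electron acceptor instead and `r_no3p` mol NO3 per mol P are consumed,
#' with the organic nitrogen returned to the fixed-nitrogen pool, so the
#' nitrate tracer loses `r_no3p - r_np` mol per mol P at the
#' remineralisation step and `r_no3p` mol per mol P over the full
#' production-to-denitrification cycle.
#'
#' @param r_cp mol C per mol P in organic matter.
#' @param r_np mol N per mol P in organic matter.
#' @param r_o2p mol O2 consumed per mol P in aerobic remineralisation.
#' @param r_no3p mol NO3 consumed per mol P as electron acceptor in
#'   denitrification (equivalently, net fixed-N loss per mol P over the
#'   full cycle).
#' @param o2_threshold suboxic switch concentration in mmol O2 m^-3;
#'   remineralisation is aerobic at or above this concentration and uses
#'   nitrate strictly below it.
#'
#' @return An object of class `ox_stoich` (a validated list).
#' @export
#' @examples
#' s <- stoich_params()
#' o2_demand_per_orgN(s) # 10.6
stoich_params <- function(r_cp = 112, r_np = 16, r_o2p = 169.6,
                          r_no3p = 119.68, o2_threshold = 5) {
  s <- list(r_cp = r_cp, r_np = r_np, r_o2p = r_o2p, r_no3p = r_no3p,
            o2_threshold = o2_threshold)
  class(s) <- "ox_stoich"
  validate_stoich(s)
  s
}

validate_stoich <- function(s) {
  num <- vapply(s, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) stop("all stoichiometric parameters must be finite scalars")
  if (any(unlist(s) <= 0)) stop("all stoichiometric ratios must be strictly positive")
  if (s$r_o2p / s$r_no3p <= 1)
    stop("r_o2p/r_no3p must exceed 1: each mole of NO3 spent must spare more than one mole of O2")
  invisible(s)
}

#' @export
print.ox_stoich <- function(x, ...) {
  cat("Organic-matter stoichiometry (molar)\n")
  cat(sprintf("  C:N:P:-O2        = %g:%g:1:%g\n", x$r_cp, x$r_np, x$r_o2p))
  cat(sprintf("  -NO3:P (denitr.) = %g   suboxic threshold = %g mmol O2 m-3\n",
              x$r_no3p, x$o2_threshold))
  cat(sprintf("  O2 avoided per org-N denitrified: %.4g; NO3 removed: %.4g; O2 per NO3: %.4f\n",
              o2_demand_per_orgN(x), no3_demand_per_orgN(x), o2_per_no3_lost(x)))
  invisible(x)
}

#' Oxygen demand of aerobic remineralisation per mole organic nitrogen
#'
#' Moles of O2 that aerobic remineralisation of organic matter containing
#' one mole of organic nitrogen would consume (and that denitrification of
#' the same material avoids): `r_o2p / r_np`, 10.6 for the default ratios.
#'
#' @param stoich an [stoich_params()] object.
#' @return mol O2 per mol organic N.
#' @export
o2_demand_per_orgN <- function(stoich) stoich$r_o2p / stoich$r_np

#' Nitrate demand of denitrification per mole organic nitrogen
#'
#' Moles of NO3 consumed as electron acceptor when organic matter containing
#' one mole of organic nitrogen is remineralised by denitrification:
#' `r_no3p / r_np`, 7.48 for the default ratios. This equals the net
#' fixed-nitrogen inventory loss per mole of organic N put through the full
#' production-to-denitrification cycle.
#'
#' @inheritParams o2_demand_per_orgN
#' @return mol NO3 per mol organic N.
#' @export
no3_demand_per_orgN <- function(stoich) stoich$r_no3p / stoich$r_np

#' Oxygen spared per mole of nitrate lost
#'
#' The conversion factor between fixed-nitrogen loss and oxygen gain:
#' `r_o2p / r_no3p` (about 1.417 for the default ratios, "about 1.4 moles
#' of oxygen per mole of nitrate"). Equals
#' `o2_demand_per_orgN / no3_demand_per_orgN`.
#'
#' @inheritParams o2_demand_per_orgN
#' @return mol O2 per mol NO3.
#' @export
o2_per_no3_lost <- function(stoich) stoich$r_o2p / stoich$r_no3p

#' Oxygen equivalent of a nitrate-inventory loss
#'
#' Converts a change in the fixed-nitrogen (nitrate) inventory into the
#' oxygen it spares: a 6.2 Pmol nitrate loss corresponds to an 8.8 Pmol
#' oxygen gain at the default ratios. Linear and odd in its argument; a
#' negative `delta_no3` (inventory gain, e.g. from nitrogen fixation)
#' yields a negative oxygen equivalent (fixation is an oxygen sink).
#'
#' @param delta_no3 nitrate inventory *decrease* (any unit; the result is in
#'   the same unit).
#' @inheritParams o2_demand_per_orgN
#' @return oxygen equivalent of the loss, same units as `delta_no3`.
#' @export
o2_equivalent_of_nitrate_loss <- function(delta_no3, stoich) {
  delta_no3 * o2_per_no3_lost(stoich)
}

#' Oxygen released by production, per mole phosphorus
#'
#' Ordinary (nitrate-fuelled) production releases the full aerobic
#' equivalent `r_o2p` per mol P, so a closed
#' production/export/aerobic-remineralisation loop is oxygen neutral.
#' Diazotroph production releases `r_o2p - r_np * r_o2p/r_no3p` (about
#' 146.9): the newly fixed nitrogen still has to be oxidised to nitrate,
#' which costs `o2_per_no3_lost()` mol O2 per mol N in the model's oxidant
#' accounting, making nitrogen fixation a net oceanic oxygen sink of
#' about 1.417 mol O2 per mol N fixed.
#'
#' @inheritParams o2_demand_per_orgN
#' @param diazotroph logical; `TRUE` for nitrogen-fixer production.
#' @return mol O2 released per mol P fixed into organic matter.
#' @export
o2_release_per_p <- function(stoich, diazotroph = FALSE) {
  if (diazotroph) stoich$r_o2p - stoich$r_np * o2_per_no3_lost(stoich)
  else stoich$r_o2p
}

#' N* nitrate-excess diagnostic
#'
#' `N* = NO3 - 16 PO4`, the nitrate excess relative to the stoichiometric
#' equivalent of phosphate. Negative values mark waters carrying a
#' denitrification-derived fixed-nitrogen deficit.
#'
#' @param no3,po4 concentrations in mmol m^-3 (vectors recycle).
#' @return N* in mmol m^-3.
#' @export
nstar <- function(no3, po4) no3 - 16 * po4
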