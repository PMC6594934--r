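#' Default six-box ocean geometry
#'
#' The smallest topology that represents the surface regimes and interior
#' reservoirs the coupled oxygen-nitrogen mechanism needs: a warm
#' low-latitude surface where nitrogen fixers can grow, a cold Southern
#' Ocean surface feeding deep-water formation (the "loophole" through which
#' nitrate deficits reach the deep ocean without meeting nitrogen
#' fixation), a northern surface box, a poorly ventilated OMZ core that is
#' suboxic with active denitrification already in the control climate, a
#' surrounding thermocline box that is oxic in the control climate but can
#' cross below the suboxic threshold under warming (the box analogue of a
#' spatially expanding oxygen minimum zone), and the deep ocean. Volumes
#' sum to 1.3e18 m^3.
#'
#' @param volumes m^3 per box, named.
#' @param surface_areas m^2 for the surface boxes.
#' @param temperatures pre-industrial box temperatures, degrees C.
#' @return An `ox_geometry` list with `n_boxes`, `labels`, `volumes`,
#'   `is_surface`, `surface_areas`, `temperatures`.
#' @export
box_geometry <- function(volumes = c(LowLatSurface = 3.0e16,
                                     SouthernOceanSurface = 1.5e16,
                                     NorthSurface = 1.0e16,
                                     OMZ = 0.9e17,
                                     Thermocline = 1.65e17,
                                     Deep = 9.9e17),
                         surface_areas = c(LowLatSurface = 2.2e14,
                                           SouthernOceanSurface = 0.9e14,
                                           NorthSurface = 0.5e14),
                         temperatures = c(LowLatSurface = 22,
                                          SouthernOceanSurface = 4,
                                          NorthSurface = 8,
                                          OMZ = 10,
                                          Thermocline = 11,
                                          Deep = 2)) {
  if (any(volumes <= 0)) stop("box volumes must be positive")
  labels <- names(volumes)
  if (is.null(labels) || any(!nzchar(labels))) stop("boxes must be named")
  is_surface <- labels %in% names(surface_areas)
  if (!any(is_surface) || all(is_surface))
    stop("need at least one surface and one interior box")
  if (length(temperatures) != length(volumes))
    stop("one temperature per box required")
  areas <- rep(0, length(volumes))
  areas[is_surface] <- surface_areas[labels[is_surface]]
  if (any(areas[is_surface] <= 0)) stop("surface areas must be positive")
  structure(list(n_boxes = length(volumes), labels = labels,
                 volumes = unname(volumes), is_surface = is_surface,
                 surface_areas = areas,
                 temperatures = unname(temperatures[labels])),
            class = "ox_geometry")
}

#' Circulation scheme: overturning loop plus bilateral mixing
#'
#' The overturning transport `psi` runs along a closed loop of boxes
#' (default: low-latitude surface -> Southern Ocean surface -> Deep ->
#' Thermocline -> low-latitude surface, i.e. deep water forms at the cold
#' southern surface and upwells through the thermocline; the OMZ core
#' hangs off the loop, ventilated only by mixing), so every box on the loop
#' receives and loses exactly `psi` m^3 yr^-1 and the scheme is volume
#' conservative by construction. Bilateral mixing exchanges equal volumes
#' both ways and is likewise conservative. The overturning limb is scaled
#' by the scenario's overturning factor at run time; mixing is constant.
#'
#' @param psi overturning transport, m^3 yr^-1 (7.9e14 is about 25 Sv).
#' @param loop character vector of box labels visited in order (closed).
#' @param mixing named list `pair = coefficient` with names like
#'   `"LowLatSurface|OMZ"`, coefficients in m^3 yr^-1.
#' @return An `ox_circulation` list.
#' @export
circulation_scheme <- function(psi = 7.9e14,
                               loop = c("LowLatSurface",
                                        "SouthernOceanSurface",
                                        "Deep", "Thermocline"),
                               mixing = list(
                                 "LowLatSurface|OMZ" = 3.5e14,
                                 "LowLatSurface|Thermocline" = 3.0e14,
                                 "OMZ|Thermocline" = 5.0e14,
                                 "LowLatSurface|NorthSurface" = 3.0e14,
                                 "NorthSurface|Deep" = 1.6e14,
                                 "SouthernOceanSurface|Deep" = 3.0e14,
                                 "Thermocline|Deep" = 2.0e14)) {
  if (psi < 0) stop("overturning transport must be non-negative")
  if (any(unlist(mixing) < 0)) stop("mixing coefficients must be non-negative")
  structure(list(psi = psi, loop = loop, mixing = mixing),
            class = "ox_circulation")
}

# Build the transport tendency operators. M[i, j] is the rate (m^3 yr^-1)
# at which water of box j's concentration enters box i, minus, on the
# diagonal, the total outflow of box i. d(conc)/dt = (M %*% conc) / V.
# Split into a psi part (scaled by the overturning factor) and a constant
# mixing part; both have zero column sums (inventory conservation) and
# zero row sums (volume conservation).
build_transport <- function(geometry, circ) {
  n <- geometry$n_boxes
  idx <- function(lbl) {
    i <- match(lbl, geometry$labels)
    if (any(is.na(i))) stop("unknown box label in circulation: ",
                            paste(lbl[is.na(i)], collapse = ", "))
    i
  }
  Mpsi <- matrix(0, n, n)
  lp <- idx(circ$loop)
  for (k in seq_along(lp)) {
    from <- lp[k]
    to <- lp[if (k == length(lp)) 1L else k + 1L]
    Mpsi[to, from] <- Mpsi[to, from] + circ$psi
    Mpsi[from, from] <- Mpsi[from, from] - circ$psi
  }
  Mmix <- matrix(0, n, n)
  for (pair in names(circ$mixing)) {
    ab <- idx(strsplit(pair, "|", fixed = TRUE)[[1]])
    k <- circ$mixing[[pair]]
    Mmix[ab[1], ab[2]] <- Mmix[ab[1], ab[2]] + k
    Mmix[ab[2], ab[1]] <- Mmix[ab[2], ab[1]] + k
    Mmix[ab[1], ab[1]] <- Mmix[ab[1], ab[1]] - k
    Mmix[ab[2], ab[2]] <- Mmix[ab[2], ab[2]] - k
  }
  check_conservative(Mpsi, "overturning loop")
  check_conservative(Mmix, "mixing")
  list(Mpsi = Mpsi, Mmix = Mmix)
}

check_conservative <- function(M, what) {
  scale <- max(abs(M), 1)
  if (max(abs(colSums(M))) > 1e-9 * scale)
    stop("non-conservative circulation (", what, "): inventory would drift")
  if (max(abs(rowSums(M))) > 1e-9 * scale)
    stop("non-conservative circulation (", what, "): volume would drift")
  invisible(TRUE)
}

#' Transport tendency of tracer concentrations
#'
#' Applies the circulation operator to a concentration matrix. For every
#' tracer the volume-weighted sum of tendencies is zero: transport alone
#' changes no global inventory.
#'
#' @param conc matrix (boxes x tracers) or vector of concentrations.
#' @param geometry an [box_geometry()] object.
#' @param circ an [circulation_scheme()] object.
#' @param psi_factor dimensionless overturning scale factor (default 1).
#' @return matrix/vector of d(conc)/dt in concentration units per year.
#' @export
transport_tendency <- function(conc, geometry, circ, psi_factor = 1) {
  op <- build_transport(geometry, circ)
  M <- op$Mmix + psi_factor * op$Mpsi
  conc <- as.matrix(conc)
  drop((M %*% conc) / geometry$volumes)
}
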