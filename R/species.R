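#' Species registry
#'
#' The model carries 12 solute and 10 solid species.  Solutes are porewater
#' concentrations in umol cm^-3 (numerically equal to mmol L^-1); solids are
#' contents of the dry sediment in umol g^-1 (organic-matter pools in carbon
#' units).  Each species records its phase, molar mass, molecular diffusivity
#' (solutes, cm^2 yr^-1 at the reference bottom-water temperature of 5 degC)
#' and its O2-equivalent: the moles of O2 consumed by complete re-oxidation of
#' one mole of the reduced species, which is the weight it carries in the
#' reduced-substance flux F_red (2 for CH4, NH4+ and S(-II), 0.5 for Mn(II),
#' 0.25 for Fe(II), 0 otherwise).
#'
#' Molecular diffusivities are a literature (Boudreau-style) compilation of
#' infinite-dilution coefficients evaluated at 5 degC; they can be overridden
#' via the `D_mol` argument.
#'
#' @param D_mol optional named numeric vector overriding molecular
#'   diffusivities (cm^2 yr^-1) for a subset of solutes.
#' @return A data frame with one row per species: `name`, `phase`
#'   ("solute"/"solid"), `molar_mass` (g mol^-1), `D_mol` (cm^2 yr^-1, NA for
#'   solids) and `o2_equivalent` (mol O2 per mol).
#' @examples
#' sp <- species_registry()
#' sum(sp$phase == "solute")  # 12
#' sum(sp$o2_equivalent)      # 6.75
#' @export
species_registry <- function(D_mol = NULL) {
  sp <- data.frame(
    name = c("O2", "NO3", "SO4", "NH4", "Mn2", "Fe2", "HS", "CH4",
             "CO2", "HCO3", "N2", "HPO4",
             "OM1", "OM2", "Mo1", "Mo2", "Foh1", "Foh2",
             "FeS", "FeS2", "Viv", "MnCO3"),
    phase = c(rep("solute", 12L), rep("solid", 10L)),
    molar_mass = c(31.998, 62.004, 96.06, 18.039, 54.938, 55.845, 33.073,
                   16.043, 44.009, 61.016, 28.014, 95.979,
                   12.011, 12.011, 86.937, 86.937, 88.852, 88.852,
                   87.91, 119.97, 501.6, 114.95),
    # ~5 degC freshwater, cm^2 yr^-1 (1e-6 cm^2 s^-1 = 31.557 cm^2 yr^-1)
    D_mol = c(382, 331, 183, 344, 117, 123, 309, 300,
              334, 192, 347, 129, rep(NA_real_, 10L)),
    o2_equivalent = c(0, 0, 0, 2, 0.5, 0.25, 2, 2,
                      0, 0, 0, 0, rep(0, 10L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(D_mol)) {
    unknown <- setdiff(names(D_mol), sp$name[sp$phase == "solute"])
    if (length(unknown))
      stop("unknown solute(s) in D_mol override: ", paste(unknown, collapse = ", "))
    sp$D_mol[match(names(D_mol), sp$name)] <- as.numeric(D_mol)
  }
  class(sp) <- c("sediagen_species", "data.frame")
  sp
}

species_index <- function(name, species = species_registry()) {
  i <- match(name, species$name)
  if (anyNA(i)) stop("unknown species: ", paste(name[is.na(i)], collapse = ", "))
  i
}

#' Convert a porewater concentration to mg per litre
#'
#' umol cm^-3 is numerically mmol L^-1, so the conversion is a single
#' multiplication by the molar mass.
#'
#' @param species species name (must exist in [species_registry()]).
#' @param c concentration in umol cm^-3 (non-negative).
#' @param registry species registry, defaults to [species_registry()].
#' @return concentration in mg L^-1.
#' @examples
#' concentration_mgL("O2", 0.180)  # 5.76 mg/L
#' @export
concentration_mgL <- function(species, c, registry = species_registry()) {
  i <- species_index(species, registry)
  if (any(c < 0)) stop("concentration must be non-negative")
  c * registry$molar_mass[i]
}

#' Inverse of [concentration_mgL()]
#' @param species species name.
#' @param mgL concentration in mg L^-1.
#' @param registry species registry.
#' @return concentration in umol cm^-3.
#' @export
concentration_from_mgL <- function(species, mgL, registry = species_registry()) {
  i <- species_index(species, registry)
  mgL / registry$molar_mass[i]
}

#' Total organic-carbon deposition in g C m^-2 yr^-1
#'
#' Sums the reactive and non-reactive organic-matter depositional fluxes
#' (both in umol C cm^-2 yr^-1) and converts to the areal carbon loading
#' customary in lake budgets.
#'
#' @param j_OM1,j_OM2 depositional fluxes of the two OM pools,
#'   umol C cm^-2 yr^-1.
#' @return g C m^-2 yr^-1.
#' @examples
#' carbon_flux_gC(623, 267)  # ~107
#' @export
carbon_flux_gC <- function(j_OM1, j_OM2) {
  if (any(j_OM1 < 0) || any(j_OM2 < 0)) stop("depositional fluxes must be non-negative")
  (j_OM1 + j_OM2) * 12.011 * 1e-6 * 1e4
}

#' Convert an O2-equivalent areal flux to gO2 m^-2 d^-1
#'
#' @param j flux in umol O2-eq cm^-2 yr^-1 (signed).
#' @return flux in gO2 m^-2 d^-1.
#' @examples
#' o2eq_flux_gO2_m2_d(411)  # ~0.36
#' @export
o2eq_flux_gO2_m2_d <- function(j) {
  j * 31.998e-6 * 1e4 / 365.25
}
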