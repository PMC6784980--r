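#' Default model parameters
#'
#' Returns the full parameter set of the Lake Baldegg configuration: physical
#' properties of the sediment column, bioturbation constants, the six primary
#' mineralization rate constants and their limitation/inhibition
#' half-saturation constants, the bimolecular constants of the secondary redox
#' reactions, mineral precipitation/dissolution constants and equilibrium
#' constants, the fixed proton activity and the rate-limiting constant `L`
#' that guards every consumption term.
#'
#' Units: depths in cm, rate constants of primary mineralization in yr^-1,
#' bimolecular constants in cm^3 umol^-1 yr^-1, half-saturation constants in
#' umol cm^-3 (solute electron acceptors) or umol g^-1 (Mn/Fe oxide pools),
#' mineral precipitation constants in umol g^-1 yr^-1, dissolution constants
#' in yr^-1.  `f_dnra` is the dimensionless fraction of the nitrate-reducing
#' carbon flow routed through dissimilatory nitrate reduction to ammonium
#' rather than denitrification.
#'
#' @param ... named overrides of individual parameters.
#' @return a named list of class `sediagen_parameters`.
#' @examples
#' p <- default_parameters()
#' p$porosity
#' p2 <- default_parameters(k_deg_CH4 = 0.1)
#' @export
default_parameters <- function(...) {
  p <- list(
    depth       = 50,       # simulated sediment depth, cm
    rho_b       = 2.48,     # dry density, g cm^-3
    porosity    = 0.84,
    sed_rate    = 0.15,     # initial (pre-eutrophication) burial velocity, cm yr^-1
    Db0         = 1,        # bioturbation coefficient at the interface, cm^2 yr^-1
    H_bio       = 0.5,      # depth of max. bioturbation gradient, cm
    tau_bio     = 1.43,     # bioturbation depth attenuation, cm
    Db_min      = 0.01,     # residual mixing, cm^2 yr^-1
    d_dbl       = 0.082,    # diffusive boundary layer thickness, cm
    # primary mineralization of the reactive OM pool, yr^-1
    k_deg_O2    = 9.1,
    k_deg_NO3   = 7.3,
    k_deg_MnO2  = 1.08e-2,
    k_deg_FeOOH = 1.08e-2,
    k_deg_SO4   = 1.44,
    k_deg_CH4   = 5.28e-2,
    # rate inhibition (half-saturation) concentrations
    K_O2        = 1e-3,     # umol cm^-3
    K_NO3       = 1e-3,     # umol cm^-3
    K_MnO2      = 16,       # umol g^-1
    K_FeOOH     = 100,      # umol g^-1
    K_SO4       = 0.1,      # umol cm^-3
    # secondary redox reactions, cm^3 umol^-1 yr^-1
    k_nhox      = 500,      # NH4 + O2
    k_mox       = 7500,     # Mn(II) + O2
    k_fox       = 1e4,      # Fe(II) + O2
    k_sox       = 160,      # S(-II) + O2
    k_chox      = 3e5,      # CH4 + O2
    k_nhmo      = 7.5e-4,   # NH4 + reactive MnO2
    k_nhmx      = 7.5e-5,   # NH4 + less-reactive MnO2
    k_nhfo      = 9.45e-4,  # NH4 + reactive FeOOH
    k_nhfx      = 9.45e-5,  # NH4 + less-reactive FeOOH
    k_fmo       = 1.5e-2,   # Fe(II) + reactive MnO2
    k_fmx       = 1.5e-3,   # Fe(II) + less-reactive MnO2
    k_smo       = 1,        # S(-II) + reactive MnO2
    k_smx       = 0.1,      # S(-II) + less-reactive MnO2
    k_sfo       = 2.5,      # S(-II) + reactive FeOOH
    k_sfx       = 0.25,     # S(-II) + less-reactive FeOOH
    k_chso      = 0.5,      # CH4 + SO4 (anaerobic CH4 oxidation)
    k_moN       = 1e3,      # Mn(II) + NO3
    # mineral phases
    k_vivpre    = 2.72e-5,  # vivianite precipitation, umol g^-1 yr^-1
    k_vivdis    = 1,        # vivianite dissolution, yr^-1
    k_EqViv     = 3e-20,    # vivianite solubility product (mol L^-1 scale)
    k_sviv      = 10,       # vivianite dissolution by S(-II), cm^3 umol^-1 yr^-1
    k_FeSpre    = 0.1,      # FeS precipitation, umol g^-1 yr^-1
    k_FeSdis    = 2e-3,     # FeS dissolution, yr^-1
    k_EqFeS     = 6.3096,   # FeS solubility (model units over H+)
    k_pyrpre    = 4,        # pyrite formation, cm^3 umol^-1 yr^-1
    k_MnCO3pre  = 0.01064,  # MnCO3 precipitation, umol g^-1 yr^-1
    k_EqHCO3CO3 = 2375e-8,  # HCO3/CO3 speciation constant (stored verbatim)
    k_EqMnCO3   = 0.022,    # MnCO3 solubility (model units)
    H_plus      = 1e-7,     # fixed proton activity (pH 7)
    L           = 1e-8,     # rate-limiting constant guarding consumption terms
    # branching fraction of nitrate reduction going to NH4 (DNRA)
    f_dnra      = 0.2,
    # organic-matter elemental ratio C:N:P:S per formula unit
    cx          = 106,
    cy          = 8,
    cz          = 0.5,
    cs          = 0.5
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "sediagen_parameters"
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants: all rate and equilibrium constants
#' non-negative, porosity strictly inside (0, 1), positive dry density, DBL
#' thickness and depth, elemental ratio positive, DNRA fraction in [0, 1].
#'
#' @param p a parameter set from [default_parameters()].
#' @return character vector of violations; empty if the set is valid.
#' @examples
#' validate_parameters(default_parameters())          # character(0)
#' validate_parameters(default_parameters(porosity = 1.2))
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    v <- c(v, paste0(names(p)[!num], ": must be a finite scalar"))
  chk <- function(cond, msg) if (isTRUE(cond)) character(0) else msg
  v <- c(v,
    chk(p$porosity > 0 && p$porosity < 1, "porosity: must lie in (0,1)"),
    chk(p$rho_b > 0,  "rho_b: must be positive"),
    chk(p$depth > 0,  "depth: must be positive"),
    chk(p$d_dbl > 0,  "d_dbl: must be positive"),
    chk(p$f_dnra >= 0 && p$f_dnra <= 1, "f_dnra: must lie in [0,1]"),
    chk(p$cx > 0, "cx: must be positive"))
  rate_names <- grep("^(k_|K_)", names(p), value = TRUE)
  for (nm in rate_names)
    if (is.numeric(p[[nm]]) && length(p[[nm]]) == 1L && !is.na(p[[nm]]) &&
        p[[nm]] < 0)
      v <- c(v, paste0(nm, ": rate/equilibrium constant must be non-negative"))
  for (nm in c("Db0", "Db_min", "H_bio", "tau_bio", "sed_rate", "L"))
    if (p[[nm]] < 0) v <- c(v, paste0(nm, ": must be non-negative"))
  v
}

#' Read a parameter file
#'
#' Parameter files are flat YAML maps `name: value`; unknown keys are
#' rejected.  The packaged default file reproduces [default_parameters()].
#'
#' @param path path to a YAML file; defaults to the packaged parameter file.
#' @return a `sediagen_parameters` list.
#' @export
read_parameters <- function(path = system.file("extdata", "parameters.yml",
                                               package = "sediagen")) {
  vals <- yaml::read_yaml(path)
  do.call(default_parameters, vals)
}

#' @export
print.sediagen_parameters <- function(x, ...) {
  cat("<sediagen parameter set>", length(x), "parameters\n")
  cat("  porosity", x$porosity, " rho_b", x$rho_b, "g/cm3  depth", x$depth, "cm\n")
  cat("  k_deg (O2, NO3, MnO2, FeOOH, SO4, CH4) =",
      x$k_deg_O2, x$k_deg_NO3, x$k_deg_MnO2, x$k_deg_FeOOH,
      x$k_deg_SO4, x$k_deg_CH4, "yr^-1\n")
  viol <- validate_parameters(x)
  if (length(viol)) cat("  INVALID:", length(viol), "violation(s)\n")
  invisible(x)
}
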