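# Derived quantities: interface fluxes (SOU, F_red, SOD), Fick's-law flux
# estimation, O2 penetration depth, production attribution by sediment age,
# element mass balances, parameter sensitivity and profile misfit.

# Internal: molecular diffusivities of the solutes as a named vector.
.dmol <- function(species = species_registry()) {
  stats::setNames(species$D_mol[match(.SOLUTES, species$name)], .SOLUTES)
}

#' Sediment-water interface fluxes at one instant
#'
#' Evaluates the diffusive-boundary-layer flux of every solute at the
#' sediment surface and assembles the oxygen budget terms: SOU (O2 flux into
#' the sediment), the per-species effluxes of the reduced substances (CH4,
#' NH4+, S(-II), Mn(II), Fe(II); positive out of the sediment), their
#' O2-equivalent combination
#' `F_red = 2 J_CH4 + 2 J_NH4 + 2 J_S + 0.5 J_Mn + 0.25 J_Fe`,
#' and `SOD = SOU + F_red`.
#'
#' @param state n x 22 concentration matrix (native units).
#' @param t decimal year (fixes the bottom-water concentrations).
#' @param scenario scenario name or object.
#' @param params parameter set.
#' @param seasonal evaluate seasonally modulated boundary concentrations.
#' @param scale optional named boundary multipliers (must match the run).
#' @return one-row data frame: `year`, `SOU`, `J_CH4`, `J_NH4`, `J_S`,
#'   `J_Mn`, `J_Fe`, `F_red`, `SOD` in gO2 m^-2 d^-1, plus the native molar
#'   effluxes `J_*_molar` (umol cm^-2 yr^-1, positive out of the sediment).
#' @export
sediment_fluxes <- function(state, t, scenario = "SQ",
                            params = default_parameters(),
                            seasonal = FALSE, scale = NULL) {
  bc <- .boundary_fun(scenario, seasonal, scale)(t)
  Dm <- .dmol()
  Jin <- dbl_flux(Dm, bc$B, state[1, .SOLUTES], params$d_dbl) # + into sediment
  eff <- -Jin   # positive out of the sediment
  sou <- o2eq_flux_gO2_m2_d(Jin[["O2"]])
  w <- c(CH4 = 2, NH4 = 2, HS = 2, Mn2 = 0.5, Fe2 = 0.25)
  # F_red counts reduced substances leaving the sediment; a reduced species
  # diffusing inward (e.g. bottom-water CH4 against an oxidized surface
  # layer) is oxidized inside and already charged to the O2 uptake.
  eq <- w * pmax(eff[names(w)], 0)
  fred <- o2eq_flux_gO2_m2_d(sum(eq))
  data.frame(year = t,
             SOU = sou,
             J_CH4 = o2eq_flux_gO2_m2_d(eq[["CH4"]]),
             J_NH4 = o2eq_flux_gO2_m2_d(eq[["NH4"]]),
             J_S = o2eq_flux_gO2_m2_d(eq[["HS"]]),
             J_Mn = o2eq_flux_gO2_m2_d(eq[["Mn2"]]),
             J_Fe = o2eq_flux_gO2_m2_d(eq[["Fe2"]]),
             F_red = fred,
             SOD = sou + fred,
             J_CH4_molar = eff[["CH4"]], J_NH4_molar = eff[["NH4"]],
             J_S_molar = eff[["HS"]], J_Mn_molar = eff[["Mn2"]],
             J_Fe_molar = eff[["Fe2"]], SOU_molar = Jin[["O2"]])
}

#' Flux table of a trajectory
#'
#' [sediment_fluxes()] evaluated at every snapshot.
#'
#' @param traj a `sediagen_trajectory`.
#' @return data frame with one row per snapshot.
#' @export
flux_table <- function(traj) {
  bf <- .boundary_fun(traj$scenario, traj$seasonal, traj$scale)
  Dm <- .dmol()
  p <- traj$params
  w <- c(CH4 = 2, NH4 = 2, HS = 2, Mn2 = 0.5, Fe2 = 0.25)
  rows <- lapply(seq_along(traj$times), function(i) {
    t <- traj$times[i]
    # seasonal modulation only applies once the seasonal segment has begun
    seas <- traj$seasonal && t >= traj$config$seasonal_start
    bc <- .boundary_fun(traj$scenario, seas, traj$scale)(t)
    top <- traj$states[i, 1, .SOLUTES]
    Jin <- dbl_flux(Dm, bc$B, top, p$d_dbl)
    eff <- -Jin
    sou <- o2eq_flux_gO2_m2_d(Jin[["O2"]])
    eq <- w * pmax(eff[names(w)], 0)   # outward contributions only
    fred <- o2eq_flux_gO2_m2_d(sum(eq))
    c(year = t, SOU = sou,
      J_CH4 = o2eq_flux_gO2_m2_d(eq[["CH4"]]),
      J_NH4 = o2eq_flux_gO2_m2_d(eq[["NH4"]]),
      J_S = o2eq_flux_gO2_m2_d(eq[["HS"]]),
      J_Mn = o2eq_flux_gO2_m2_d(eq[["Mn2"]]),
      J_Fe = o2eq_flux_gO2_m2_d(eq[["Fe2"]]),
      F_red = fred, SOD = sou + fred)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Porewater flux from a discrete concentration profile (Fick's first law)
#'
#' Fits a straight line to the concentration profile over the near-interface
#' window and returns `-phi * D_sed * dC/dx`: the downward-positive Fickian
#' flux, consistent with [dbl_flux()] (species leaving the sediment give
#' negative values).
#'
#' @param depth_cm depths of the profile points, cm (positive down).
#' @param conc concentrations, umol cm^-3.
#' @param D_mol molecular diffusivity of the species, cm^2 yr^-1.
#' @param phi porosity.
#' @param window fit window from the interface, cm (default 2).
#' @return flux in umol cm^-2 yr^-1, positive into the sediment.
#' @examples
#' fick_flux_from_profile(c(0.5, 1, 1.5), c(1, 2, 3), D_mol = 300, phi = 0.84)
#' @export
fick_flux_from_profile <- function(depth_cm, conc, D_mol, phi = 0.84,
                                   window = 2) {
  sel <- depth_cm <= window
  if (sum(sel) < 2) stop("need at least 2 profile points within the window")
  x <- depth_cm[sel]
  if (length(unique(x)) < 2) stop("degenerate profile: all depths equal")
  b <- stats::coef(stats::lm(conc[sel] ~ x))[[2]]
  -phi * effective_solute_diffusivity(D_mol, phi) * b
}

#' Oxygen penetration depth
#'
#' Shallowest depth at which porewater O2 falls below the threshold
#' (default 0.1 umol L^-1 = 1e-4 umol cm^-3), linearly interpolated between
#' grid nodes; 0 if the surface cell is already below the threshold.
#'
#' @param state n x 22 concentration matrix, or a numeric O2 profile.
#' @param grid the `sediagen_grid` of the state.
#' @param threshold umol cm^-3.
#' @return depth in mm.
#' @export
o2_penetration_depth <- function(state, grid, threshold = 1e-4) {
  o2 <- if (is.matrix(state)) state[, "O2"] else state
  x <- grid$x
  below <- which(o2 < threshold)
  if (!length(below)) return(grid$depth * 10)
  i <- below[1]
  if (i == 1) return(0)
  frac <- (o2[i - 1] - threshold) / (o2[i - 1] - o2[i])
  10 * (x[i - 1] + frac * (x[i] - x[i - 1]))
}

# Internal: gross volumetric production profiles (umol cm^-3 porewater yr^-1)
# of CH4 or NH4 for one state.
.production_profile <- function(state, p, species) {
  ctx <- .reaction_context(p)
  C <- state[, .SPECIES, drop = FALSE]
  Csolid <- C[, .SOLIDS, drop = FALSE]
  Cpw <- C
  Cpw[, .SOLIDS] <- Cpw[, .SOLIDS] * ctx$m_phi
  R <- .reaction_extents(Cpw, Csolid, p, ctx)
  S <- ctx$S
  pos <- pmax(S[, species], 0)           # production entries only
  as.vector(R %*% pos)
}

#' Depth-to-age mapping from the burial history
#'
#' Integrates the time-dependent sedimentation rate backwards from
#' `eval_year`: the age of the sediment at depth x is the time elapsed since
#' the material now at x was deposited at the interface.  Depths below the
#' total accumulation since the simulation start are extrapolated with the
#' earliest sedimentation rate.
#'
#' @param depth_cm depths, cm.
#' @param eval_year evaluation year.
#' @param scenario scenario name or object.
#' @return ages in years.
#' @export
sediment_age <- function(depth_cm, eval_year, scenario = "SQ") {
  bp <- .breakpoints(.get_scenario(scenario), "sed_rate")
  tt <- seq(eval_year, eval_year - 400, by = -0.1)
  v <- stats::approx(bp$years, bp$values, xout = tt, rule = 2)$y
  cum <- cumsum(c(0, 0.05 * (v[-1] + v[-length(v)])))  # trapezoid, dt = 0.1
  age <- stats::approx(cum, eval_year - tt, xout = depth_cm, rule = 2)$y
  age
}

#' Production attributed to sediment age
#'
#' Splits the gross volumetric production of a species (CH4 or NH4) at
#' `eval_year` into bins of sediment age since deposition, using the
#' scenario's burial history to map depth to age.  Shares are the fraction
#' of the depth-integrated production per bin.
#'
#' @param traj a `sediagen_trajectory`.
#' @param species `"CH4"` or `"NH4"` (any species with a production channel).
#' @param eval_year evaluation year.
#' @param bin_edges age bin edges in years (default 0-2, 2-20, >20).
#' @return data frame: `age_min`, `age_max`, `production`
#'   (umol cm^-2 yr^-1, porewater-volume production integrated over depth)
#'   and `share`.
#' @export
production_by_age <- function(traj, species = "CH4", eval_year = 2015,
                              bin_edges = c(0, 2, 20, Inf)) {
  if (eval_year < traj$times[1])
    stop("eval_year precedes the trajectory start")
  S <- state_at(traj, eval_year)
  prod <- .production_profile(S, traj$params, species)
  g <- traj$grid
  areal <- prod * traj$params$porosity * g$h   # umol cm^-2 yr^-1 per cell
  age <- sediment_age(g$x, eval_year, traj$scenario)
  bins <- cut(age, bin_edges, include.lowest = TRUE, right = TRUE)
  tot <- sum(areal)
  agg <- tapply(areal, bins, sum, default = 0)
  data.frame(age_min = bin_edges[-length(bin_edges)],
             age_max = bin_edges[-1],
             production = as.vector(agg),
             share = as.vector(agg) / tot)
}

#' Element mass balance over a time window
#'
#' Budget of one element (C, N, P, S, Fe or Mn) between two snapshot years:
#' boundary influx and efflux at the sediment-water interface, burial export
#' across the bottom of the modelled column, and the change of the standing
#' stock.  The residual (influx - efflux - burial - storage change) is
#' reported as a fraction of the gross throughput.  The nitrogen budget
#' includes the N2 channel (denitrification product escaping to the water
#' column) as an ordinary species flux.
#'
#' @param traj a `sediagen_trajectory`.
#' @param element one of `"C"`, `"N"`, `"P"`, `"S"`, `"Fe"`, `"Mn"`.
#' @param window two years spanned by the trajectory.
#' @return list with the budget terms (mol m^-2 over the window, expressed
#'   as umol cm^-2) and `residual_fraction`.
#' @export
element_mass_balance <- function(traj, element = "C",
                                 window = range(traj$times)) {
  p <- traj$params
  g <- traj$grid
  E <- element_composition(p)[, element]
  eps <- c(rep(p$porosity, 12L), rep(p$rho_b * (1 - p$porosity), 10L))
  Dm <- .dmol()
  idx <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (length(idx) < 2) stop("window must span at least two snapshots")
  tt <- traj$times[idx]
  stock <- influx <- outflux <- burial <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    S <- traj$states[i, , ]
    stock[k] <- sum((t(S) * eps * E) %*% g$h)
    seas <- traj$seasonal && tt[k] >= traj$config$seasonal_start
    bc <- .boundary_fun(traj$scenario, seas, traj$scale)(tt[k])
    Js <- dbl_flux(Dm, bc$B, S[1, 1:12], p$d_dbl)       # + into sediment
    Ftop <- sum(Js * E[.SOLUTES]) + sum(bc$J * E[.SOLIDS])
    influx[k] <- sum(pmax(Js, 0) * E[.SOLUTES]) + sum(bc$J * E[.SOLIDS])
    outflux[k] <- influx[k] - Ftop                      # efflux = in - net
    burial[k] <- sum(eps * E * S[g$n, ]) * bc$v
  }
  trap <- function(y) sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
  IN <- trap(influx); OUT <- trap(outflux); BUR <- trap(burial)
  dM <- stock[length(stock)] - stock[1]
  gross <- max(IN, OUT + BUR + abs(dM), 1e-12)
  list(element = element, window = window,
       influx = IN, efflux = OUT, burial = BUR, storage_change = dM,
       residual = IN - OUT - BUR - dM,
       residual_fraction = abs(IN - OUT - BUR - dM) / gross)
}

#' Normalized sensitivity of the areal hypolimnetic mineralization output
#'
#' Central-difference sensitivity of the model's oxygen-demand output (AHM,
#' operationalized as SOD = SOU + F_red at the evaluation year of the
#' baseline scenario) to a +/-1 percent perturbation of one rate constant or
#' of the reactive organic-matter depositional flux:
#' `S = [(AHM+ - AHM-) / (2 AHM0)] / delta`.
#'
#' @param parameter a name from [default_parameters()] (e.g. `"k_deg_CH4"`)
#'   or `"OM1_flux"` for the OM1 depositional boundary flux.
#' @param config solver configuration.
#' @param params baseline parameter set.
#' @param scenario baseline scenario.
#' @param eval_year year at which AHM is evaluated (default 2015).
#' @param delta relative perturbation (default 0.01).
#' @param cache reuse cached runs.
#' @return list with `parameter`, `baseline` AHM, perturbed values and the
#'   normalized `sensitivity`.
#' @export
sensitivity_AHM <- function(parameter, config = solver_config(),
                            params = default_parameters(), scenario = "SQ",
                            eval_year = 2015, delta = 0.01, cache = TRUE) {
  ahm <- function(pp, sc_scale) {
    traj <- run_scenario(scenario, config, pp, end = eval_year,
                         scale = sc_scale, cache = cache)
    ft <- sediment_fluxes(state_at(traj, eval_year), eval_year, scenario,
                          pp, scale = sc_scale)
    ft$SOD
  }
  perturbed <- function(f) {
    if (identical(parameter, "OM1_flux")) {
      list(p = params, scale = c(OM1 = f))
    } else {
      if (!parameter %in% names(params)) stop("unknown parameter: ", parameter)
      pp <- params
      pp[[parameter]] <- pp[[parameter]] * f
      list(p = pp, scale = NULL)
    }
  }
  a0 <- ahm(params, NULL)
  up <- perturbed(1 + delta); dn <- perturbed(1 - delta)
  ap <- ahm(up$p, up$scale)
  am <- ahm(dn$p, dn$scale)
  if (abs(a0) < 1e-12)
    return(list(parameter = parameter, baseline = a0, upper = ap, lower = am,
                sensitivity = NA_real_,
                note = "baseline AHM is zero; sensitivity undefined"))
  list(parameter = parameter, baseline = a0, upper = ap, lower = am,
       sensitivity = (ap - am) / (2 * a0) / delta)
}

#' Misfit between a modelled and an observed profile
#'
#' Mean absolute relative error after linear interpolation of the model onto
#' the observation depths.
#'
#' @param model_depth,model_value modelled profile.
#' @param obs_depth,obs_value observed profile.
#' @return list with `percent` (mean absolute relative error x 100) and a
#'   `residuals` data frame.
#' @examples
#' profile_misfit(1:10, 1:10, 1:10, 1.1 * (1:10))$percent  # ~9.1
#' @export
profile_misfit <- function(model_depth, model_value, obs_depth, obs_value) {
  lo <- max(min(model_depth), min(obs_depth))
  hi <- min(max(model_depth), max(obs_depth))
  sel <- obs_depth >= lo & obs_depth <= hi
  if (!any(sel)) stop("no overlap between model and observation depths")
  m <- stats::approx(model_depth, model_value, xout = obs_depth[sel])$y
  o <- obs_value[sel]
  rel <- abs(m - o) / pmax(abs(o), 1e-12)
  list(percent = 100 * mean(rel),
       residuals = data.frame(depth_cm = obs_depth[sel], observed = o,
                              modelled = m, residual = m - o))
}
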