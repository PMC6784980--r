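# Transient upper-boundary conditions: the 1860-2018 eutrophication/aeration
# history shared by all scenarios, the four post-2018 management branches,
# and the optional seasonal cosine modulation.

# Shared history breakpoints (calendar year, value).  Values between
# breakpoints are linearly interpolated; beyond the last breakpoint they are
# held constant.  The pre-1860 decade is held at the 1860 values.
.history_years <- c(1850, 1860, 1890, 1900, 1950, 1982, 1985, 2018)

# `lerp50` carries the 1900->1982 line through the 1950 node, which exists
# only because OM deposition and the sedimentation rate step there.
.lerp50 <- function(a, b) a + (b - a) * 50 / 82

.history <- list(
  # solutes: bottom-water concentrations, umol cm^-3
  O2   = c(0.180, 0.180, 1e-5,  1e-5,  1e-5,  1e-5,  0.1,  0.1),
  NO3  = c(0.030, 0.030, 0.030, 1e-5,  1e-5,  1e-5,  0.1,  0.1),
  SO4  = c(0.035, 0.035, 0.035, 1e-5,  1e-5,  1e-5,  0.11, 0.11),
  NH4  = c(1e-4,  1e-4,  1e-4,  0.15,  .lerp50(0.15, 0.5), 0.5, 0.1, 0.1),
  Mn2  = c(1e-10, 1e-10, 1e-10, 0.08,  0.08,  0.08,  0.01, 0.01),
  Fe2  = c(1e-10, 1e-10, 1e-10, 0.08,  0.08,  0.08,  0.01, 0.01),
  HS   = c(1e-10, 1e-10, 1e-10, 0.03,  .lerp50(0.03, 0.034), 0.034,
           1e-10, 1e-10),
  CH4  = c(1e-10, 1e-10, 1e-10, 0.1,   .lerp50(0.1, 0.8), 0.8, 0.05, 0.05),
  CO2  = rep(0.01, 8), HCO3 = rep(1, 8), N2 = rep(0.1, 8),
  HPO4 = rep(0.001, 8),
  # solids: depositional fluxes, umol cm^-2 yr^-1 ("from 1950" step for OM
  # and the sedimentation rate)
  OM1  = c(192.5, 192.5, 407.75, 479.5, 623,  623,  623,  623),
  OM2  = c(82.5,  82.5,  174.75, 205.5, 267,  267,  267,  267),
  Mo1  = c(7, 7, 7, 7, .lerp50(7, 10), 10, 10, 10),
  Mo2  = c(1, 1, 1, 1, .lerp50(1, 1.25), 1.25, 1.25, 1.25),
  Foh1 = c(18, 18, 18, 18, .lerp50(18, 23), 23, 23, 23),
  Foh2 = c(3.3, 3.3, 3.3, 3.3, .lerp50(3.3, 3.6), 3.6, 3.6, 3.6),
  FeS  = rep(1e-10, 8), FeS2 = rep(1e-10, 8), Viv = rep(1e-5, 8),
  MnCO3 = rep(0, 8),
  # auxiliary forcings
  Db0  = c(1, 1, 1, 0, 0, 0, 0.2, 0.7),
  sed_rate = c(0.15, 0.15, 0.15, 0.18, 0.33, 0.33, 0.33, 0.33)
)

# Post-2018 branch targets (value reached at `year`, then held).  Entries are
# lists (year, value); multiple entries give extra breakpoints.
.branches <- list(
  SQ = list(),    # all boundary conditions held at 2018 values
  M = list(O2 = c(2030, 0.15), NO3 = c(2030, 0.1), SO4 = c(2030, 0.11),
           NH4 = c(2030, 0.05), Mn2 = c(2030, 0.005), Fe2 = c(2030, 0.005),
           HS = c(2030, 1e-10), CH4 = c(2030, 0.05),
           OM1 = c(2030, 350), OM2 = c(2030, 150),
           Mo1 = c(2030, 8), Mo2 = c(2030, 1.25),
           Foh1 = c(2030, 20), Foh2 = c(2030, 3.4),
           Db0 = c(2030, 1), sed_rate = c(2030, 0.22)),
  O = list(O2 = c(2030, 0.2), NO3 = c(2030, 0.1), SO4 = c(2030, 0.11),
           NH4 = c(2030, 1e-4), Mn2 = c(2030, 1e-10), Fe2 = c(2030, 1e-10),
           HS = c(2030, 1e-10), CH4 = c(2030, 1e-10),
           OM1 = c(2030, 210), OM2 = c(2030, 90),
           Mo1 = c(2030, 7), Mo2 = c(2030, 1),
           Foh1 = c(2030, 18), Foh2 = c(2030, 3.3),
           Db0 = c(2030, 1), sed_rate = c(2030, 0.15)),
  # Aeration stops: the O2 boundary collapses by 2020 ("from 2020"); the
  # other boundary changes follow the common 2018->2030 ramp convention.
  # The bottom water accumulates reduced substances (NH4 300, CH4 100,
  # Mn/Fe 80, S(-II) 30 umol L^-1) and bioturbation ceases.
  NoAa = list(O2 = c(2020, 1e-5), NO3 = c(2030, 1e-5), SO4 = c(2030, 1e-5),
              NH4 = c(2030, 0.3), Mn2 = c(2030, 0.08), Fe2 = c(2030, 0.08),
              HS = c(2030, 0.03), CH4 = c(2030, 0.1),
              OM1 = c(2030, 623), OM2 = c(2030, 267),
              Mo1 = c(2030, 7), Mo2 = c(2030, 1),
              Foh1 = c(2030, 18), Foh2 = c(2030, 3.3),
              Db0 = c(2030, 0), sed_rate = c(2030, 0.33))
)

# Seasonal cosine modulation groups; annual mean of each factor is 1.
.seasonal_amplitude <- c(
  O2 = 0.9, NO3 = 0.3, SO4 = 0.1,
  NH4 = -0.75, Mn2 = -0.75, Fe2 = -0.75, CH4 = -0.75,
  OM1 = -0.5, OM2 = -0.5, Mo1 = -0.5, Mo2 = -0.5, Foh1 = -0.5, Foh2 = -0.5)

#' Seasonal boundary-modulation factor
#'
#' Dimensionless cosine multipliers applied to the annual-mean boundary
#' conditions: oxygen peaks at winter overturn (t = 0, factor 1.9) and
#' collapses in late summer stratification (t = 0.5, factor 0.1); the
#' reduced solutes and the depositional fluxes peak mid-year.  Every factor
#' has an annual mean of exactly 1, so seasonal and non-seasonal runs
#' receive identical annual loads.
#'
#' @param group one of `"O2"`, `"NO3"`, `"SO4"`, `"reduced"` (NH4, Mn(II),
#'   Fe(II), CH4) or `"solids"` (the six depositional fluxes); species names
#'   belonging to a group are also accepted.
#' @param t time in (decimal) years; the phase origin is January 1.
#' @return multiplier >= 0.
#' @examples
#' seasonal_factor("O2", 0)    # 1.9
#' seasonal_factor("O2", 0.5)  # 0.1
#' @export
seasonal_factor <- function(group, t) {
  a <- switch(group,
              O2 = 0.9, NO3 = 0.3, SO4 = 0.1,
              reduced = -0.75, NH4 = -0.75, Mn2 = -0.75, Fe2 = -0.75,
              CH4 = -0.75,
              solids = -0.5, OM1 = -0.5, OM2 = -0.5, Mo1 = -0.5,
              Mo2 = -0.5, Foh1 = -0.5, Foh2 = -0.5,
              stop("unknown seasonal group: ", group))
  1 + a * cos(2 * pi * t)
}

#' The four lake-management scenarios
#'
#' All scenarios share the same 1850-2018 eutrophication and aeration
#' history.  After 2018:
#' \describe{
#'   \item{SQ}{status quo: all boundary conditions held at 2018 values.}
#'   \item{M}{mesotrophic production: TOC deposition ramped down to
#'     60 gC m^-2 yr^-1 and bottom-water O2 raised to 0.15 umol cm^-3
#'     (4.8 mg L^-1) linearly over 2018-2030, then held.}
#'   \item{O}{oligotrophic production: TOC deposition to 36 gC m^-2 yr^-1,
#'     O2 to 0.2 umol cm^-3 (6.4 mg L^-1).}
#'   \item{NoAa}{no artificial aeration: O2 collapses to numerical zero by
#'     2020, NO3/SO4 decline, reduced substances accumulate in the bottom
#'     water, bioturbation ceases; TOC deposition unchanged.}
#' }
#'
#' @return named list of `sediagen_scenario` objects.
#' @export
scenario_catalog <- function() {
  out <- lapply(names(.branches), function(nm) {
    sc <- list(name = nm, history_years = .history_years,
               history = .history, branch = .branches[[nm]])
    class(sc) <- "sediagen_scenario"
    sc
  })
  stats::setNames(out, names(.branches))
}

.get_scenario <- function(scenario) {
  if (inherits(scenario, "sediagen_scenario")) return(scenario)
  cat_ <- scenario_catalog()
  if (!scenario %in% names(cat_))
    stop("unknown scenario: ", scenario,
         " (available: ", paste(names(cat_), collapse = ", "), ")")
  cat_[[scenario]]
}

# Breakpoint table (year, value) for one forcing variable under a scenario.
.breakpoints <- function(scenario, var) {
  sc <- .get_scenario(scenario)
  if (!var %in% names(sc$history)) stop("unknown boundary variable: ", var)
  yrs <- sc$history_years
  val <- sc$history[[var]]
  br <- sc$branch[[var]]
  if (!is.null(br)) {
    yrs <- c(yrs, br[1])
    val <- c(val, br[2])
  }
  list(years = yrs, values = val)
}

#' Evaluate a boundary condition at a point in time
#'
#' Piecewise-linear interpolation between the breakpoints of the scenario's
#' boundary timeline, with constant extrapolation beyond the first/last
#' breakpoint.  Solute variables return bottom-water concentrations
#' (umol cm^-3), solid variables depositional fluxes (umol cm^-2 yr^-1);
#' `"Db0"` and `"sed_rate"` return the interface bioturbation coefficient
#' and burial velocity.
#'
#' @param var species or forcing name.
#' @param t decimal year(s).
#' @param scenario scenario name or object (default `"SQ"`).
#' @param seasonal apply the seasonal cosine modulation (only to the groups
#'   that carry one).
#' @return numeric value(s) in native units.
#' @examples
#' boundary_value("O2", 1860)            # 0.180
#' boundary_value("OM1", 2030, "M")      # 350
#' @export
boundary_value <- function(var, t, scenario = "SQ", seasonal = FALSE) {
  bp <- .breakpoints(scenario, var)
  v <- stats::approx(bp$years, bp$values, xout = t, rule = 2)$y
  if (seasonal && var %in% names(.seasonal_amplitude))
    v <- v * (1 + .seasonal_amplitude[[var]] * cos(2 * pi * t))
  v
}

#' @export
print.sediagen_scenario <- function(x, ...) {
  cat("<sediagen scenario>", x$name, "\n")
  if (length(x$branch)) {
    cat("  post-2018 overrides:\n")
    for (nm in names(x$branch))
      cat("   ", nm, "->", x$branch[[nm]][2], "by", x$branch[[nm]][1], "\n")
  } else cat("  boundary conditions held at 2018 values\n")
  invisible(x)
}

# Internal: fast boundary evaluator.  Returns a function(t) yielding the
# full boundary set: B (12 solute concentrations), J (10 solid fluxes),
# Db0 and burial velocity v -- seasonally modulated if requested.
.boundary_fun <- function(scenario, seasonal = FALSE, scale = NULL) {
  sc <- .get_scenario(scenario)
  vars <- c(.SPECIES, "Db0", "sed_rate")
  bps <- lapply(vars, function(v) .breakpoints(sc, v))
  names(bps) <- vars
  amp <- stats::setNames(numeric(length(vars)), vars)
  if (seasonal) amp[names(.seasonal_amplitude)] <- .seasonal_amplitude
  mult <- stats::setNames(rep(1, length(vars)), vars)
  if (!is.null(scale)) {
    unknown <- setdiff(names(scale), vars)
    if (length(unknown))
      stop("unknown boundary variable(s) in scale: ",
           paste(unknown, collapse = ", "))
    mult[names(scale)] <- scale
  }
  function(t) {
    v <- vapply(bps, function(bp)
      stats::approx(bp$years, bp$values, xout = t, rule = 2)$y, numeric(1))
    v <- v * mult
    if (seasonal) v <- v * (1 + amp * cos(2 * pi * t))
    list(B = v[.SOLUTES], J = v[.SOLIDS],
         Db0 = v[["Db0"]], v = v[["sed_rate"]])
  }
}
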