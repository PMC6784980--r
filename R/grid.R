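#' Build the stretched sediment grid
#'
#' Cell-centred finite-volume grid over 0 to `depth` cm, positive downward,
#' x = 0 at the sediment-water interface.  Cell interfaces follow a geometric
#' stretching law with spacing proportional to (x + stretch): near-surface
#' cells resolve the sub-millimetre oxic layer while deep cells grow
#' gradually.  At the reference resolution (`n_nodes = 500`,
#' `stretch = 0.4`) the spacing is 0.004-0.013 cm within the top centimetre,
#' ~0.29 cm at 30 cm and ~0.48 cm at 50 cm.
#'
#' @param n_nodes number of cells (>= 20).
#' @param depth maximum depth in cm.
#' @param stretch surface length scale x0 in cm; smaller values concentrate
#'   more cells near the interface.
#' @return object of class `sediagen_grid`: cell centres `x`, interfaces
#'   `x_int`, widths `h`, centre spacings `dxc`, `n`, `depth`.
#' @examples
#' g <- build_grid(80)
#' head(diff(g$x_int))
#' @export
build_grid <- function(n_nodes = 80, depth = 50, stretch = 0.2) {
  if (n_nodes < 20) stop("n_nodes must be at least 20")
  if (depth <= 0 || stretch <= 0) stop("depth and stretch must be positive")
  r <- (1 + depth / stretch)^(1 / n_nodes)
  x_int <- stretch * (r^(0:n_nodes) - 1)
  x_int[n_nodes + 1] <- depth
  h <- diff(x_int)
  if (h[1] > 0.1)
    stop("grid too coarse to resolve the near-interface cell; ",
         "increase n_nodes or decrease stretch")
  x <- (x_int[-1] + x_int[-(n_nodes + 1)]) / 2
  g <- list(x = x, x_int = x_int, h = h, dxc = diff(x),
            n = n_nodes, depth = depth, stretch = stretch)
  class(g) <- "sediagen_grid"
  g
}

#' @export
print.sediagen_grid <- function(x, ...) {
  cat("<sediagen grid>", x$n, "cells over", x$depth, "cm;",
      "first cell", signif(x$h[1], 3), "cm, last", signif(x$h[x$n], 3), "cm\n")
  invisible(x)
}

#' Depth profile of the bioturbation coefficient
#'
#' A tanh-shaped decay from its interface value `Db0` to the residual
#' `Db_min`, with the steepest gradient at depth `H_bio` and attenuation
#' scale `tau_bio`:
#' `Db(x) = Db0 * (1 - tanh((x - H)/tau)) / (1 - tanh(-H/tau)) + Db_min`.
#'
#' @param x depth(s) in cm.
#' @param Db0 interface value, cm^2 yr^-1 (time-dependent in transient runs).
#' @param p parameter set (supplies `H_bio`, `tau_bio`, `Db_min`).
#' @return bioturbation coefficient(s), cm^2 yr^-1.
#' @examples
#' bioturbation_coefficient(0, 1, default_parameters())   # Db0 + Db_min
#' bioturbation_coefficient(20, 1, default_parameters())  # ~Db_min
#' @export
bioturbation_coefficient <- function(x, Db0, p) {
  Db0 * (1 - tanh((x - p$H_bio) / p$tau_bio)) /
    (1 - tanh(-p$H_bio / p$tau_bio)) + p$Db_min
}

#' Tortuosity-corrected sediment diffusivity
#'
#' `D_sed = D_mol / (1 - ln(phi^2))`; the logarithm is natural (the
#' Boudreau tortuosity relation this expression reproduces).
#'
#' @param D_mol molecular diffusivity, cm^2 yr^-1.
#' @param phi porosity in (0, 1).
#' @return effective diffusivity in the porewater, cm^2 yr^-1.
#' @examples
#' effective_solute_diffusivity(380, 0.84) / 380  # ~0.74
#' @export
effective_solute_diffusivity <- function(D_mol, phi) {
  if (any(phi <= 0 | phi >= 1)) stop("porosity must lie in (0,1)")
  D_mol / (1 - log(phi^2))
}

#' Solute flux through the diffusive boundary layer
#'
#' Linear diffusion across the stagnant film of thickness `d_dbl` between
#' the bottom water (concentration `B`) and the sediment surface
#' (concentration `C0`); positive into the sediment.
#'
#' @param D_mol molecular diffusivity, cm^2 yr^-1.
#' @param B bottom-water concentration, umol cm^-3.
#' @param C0 sediment-surface concentration, umol cm^-3.
#' @param d_dbl boundary-layer thickness, cm.
#' @return flux in umol cm^-2 yr^-1, positive downward.
#' @examples
#' dbl_flux(400, 0.1, 0, 0.082)  # ~488
#' @export
dbl_flux <- function(D_mol, B, C0, d_dbl) {
  if (any(d_dbl <= 0)) stop("d_dbl must be positive")
  D_mol * (B - C0) / d_dbl
}

#' Transport coefficients on a grid
#'
#' Effective diffusivities at the interior cell interfaces for every
#' species: bioturbation mixes both solids and solutes, solutes additionally
#' carry the tortuosity-corrected molecular diffusivity.
#'
#' @param grid a `sediagen_grid`.
#' @param p parameter set.
#' @param Db0 interface bioturbation coefficient (cm^2 yr^-1).
#' @param species species registry.
#' @return list with `D_int` ((n-1) x species matrix, cm^2 yr^-1),
#'   `Db_shape` (unit-Db0 bioturbation profile at interior interfaces),
#'   `D_sed` (named solute vector), `Db` (profile at cell centres).
#' @export
transport_coefficients <- function(grid, p, Db0 = p$Db0,
                                   species = species_registry()) {
  xi <- grid$x_int[2:grid$n]   # interior interfaces
  Db_int <- bioturbation_coefficient(xi, Db0, p)
  D_sed <- effective_solute_diffusivity(
    stats::setNames(species$D_mol[match(.SOLUTES, species$name)], .SOLUTES),
    p$porosity)
  D_int <- matrix(Db_int, grid$n - 1, length(.SPECIES),
                  dimnames = list(NULL, .SPECIES))
  D_int[, .SOLUTES] <- sweep(D_int[, .SOLUTES], 2, D_sed, "+")
  list(D_int = D_int,
       Db_shape = (bioturbation_coefficient(xi, 1, p) - p$Db_min),
       D_sed = D_sed,
       Db = bioturbation_coefficient(grid$x, Db0, p))
}

# Internal fast transport kernel.
#
# C       : n x 22 matrix, native units
# eps     : length-22 carrier density (phi for solutes, rho_b*(1-phi) for solids)
# D_int   : (n-1) x 22 interface diffusivities
# v       : burial velocity (cm yr^-1, >= 0)
# F_top   : length-22 boundary flux per bulk area (umol cm^-2 yr^-1 for
#           solutes; umol g^-1 * g cm^-2 yr^-1 i.e. umol cm^-2 yr^-1 for solids)
# Returns tendencies (native units yr^-1) with top/bottom fluxes as attributes.
.transport_kernel <- function(C, grid, eps, D_int, v, F_top) {
  n <- grid$n
  epsm <- matrix(eps, n - 1, length(eps), byrow = TRUE)
  Fd <- -epsm * D_int * (C[-1, , drop = FALSE] - C[-n, , drop = FALSE]) / grid$dxc
  Fa <- epsm * v * C[-n, , drop = FALSE]     # upwind from above (v >= 0)
  Fi <- Fd + Fa
  F_bot <- eps * v * C[n, ]
  dflux <- rbind(F_top, Fi, deparse.level = 0) -
           rbind(Fi, F_bot, deparse.level = 0)
  dC <- dflux / outer(grid$h, eps)
  attr(dC, "flux_top") <- F_top
  attr(dC, "flux_bottom") <- F_bot
  dC
}

#' Transport tendency of the full state
#'
#' Conservative finite-volume discretization of diffusion (bioturbation plus
#' tortuosity-corrected molecular diffusion for solutes), burial advection
#' (first-order upwind) and the boundary conditions: solutes exchange with
#' the bottom water through the diffusive boundary layer, solids receive the
#' depositional flux, and the bottom boundary imposes a zero diffusive
#' gradient with burial outflow retained.
#'
#' @param state n x 22 concentration matrix (native units), columns named by
#'   species.
#' @param grid a `sediagen_grid`.
#' @param p parameter set.
#' @param boundary list with `B` (named bottom-water concentrations for the
#'   12 solutes, umol cm^-3) and `J` (named depositional fluxes for the 10
#'   solids, umol cm^-2 yr^-1).
#' @param v burial velocity, cm yr^-1.
#' @param Db0 interface bioturbation coefficient, cm^2 yr^-1.
#' @param coeffs optional precomputed [transport_coefficients()] (with
#'   matching `Db0`); computed on the fly if `NULL`.
#' @return n x 22 tendency matrix (native units per year), with attributes
#'   `flux_top` and `flux_bottom` (umol cm^-2 yr^-1 per bulk area).
#' @export
transport_tendency <- function(state, grid, p, boundary, v = p$sed_rate,
                               Db0 = p$Db0, coeffs = NULL) {
  if (!is.matrix(state) || nrow(state) != grid$n)
    stop("state must be an n x species matrix matching the grid")
  state <- state[, .SPECIES, drop = FALSE]
  if (is.null(coeffs)) coeffs <- transport_coefficients(grid, p, Db0)
  sp <- species_registry()
  D_mol <- stats::setNames(sp$D_mol[match(.SOLUTES, sp$name)], .SOLUTES)
  m <- p$rho_b * (1 - p$porosity)
  eps <- c(rep(p$porosity, 12L), rep(m, 10L))
  F_top <- numeric(22L)
  F_top[1:12] <- dbl_flux(D_mol, boundary$B[.SOLUTES], state[1, .SOLUTES], p$d_dbl)
  F_top[13:22] <- boundary$J[.SOLIDS]
  .transport_kernel(state, grid, eps, coeffs$D_int, v, F_top)
}
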