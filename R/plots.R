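# Base-graphics views of trajectories: depth profiles and flux time series.

#' Plot depth profiles of selected species
#'
#' @param traj a `sediagen_trajectory`.
#' @param species species to draw (default the F_red solutes and O2).
#' @param year snapshot year.
#' @param max_depth plotted depth range, cm.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the list of plotted profiles.
#' @export
plot_profiles <- function(traj, species = c("O2", "CH4", "NH4", "Fe2", "Mn2",
                                            "SO4"),
                          year = 2015, max_depth = 30, ...) {
  S <- state_at(traj, year)
  x <- traj$grid$x
  sel <- x <= max_depth
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(species)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  out <- list()
  for (sp in species) {
    v <- S[sel, sp]
    graphics::plot(v, x[sel], type = "l", ylim = c(max_depth, 0),
                   xlab = paste0(sp, " (umol cm-3 / umol g-1)"),
                   ylab = "depth (cm)", main = paste(sp, year), ...)
    out[[sp]] <- data.frame(depth_cm = x[sel], value = v)
  }
  invisible(out)
}

#' Plot the oxygen-budget flux trajectories
#'
#' Draws SOU, F_red and SOD (gO2 m^-2 d^-1) against time.
#'
#' @param ft a flux table from [flux_table()] (or a trajectory, converted
#'   on the fly).
#' @param ... further arguments passed to [graphics::matplot()].
#' @return the flux table, invisibly.
#' @export
plot_fluxes <- function(ft, ...) {
  if (inherits(ft, "sediagen_trajectory")) ft <- flux_table(ft)
  graphics::matplot(ft$year, ft[, c("SOU", "F_red", "SOD")], type = "l",
                    lty = 1, col = c("steelblue", "firebrick", "black"),
                    xlab = "year", ylab = "flux (gO2 m-2 d-1)", ...)
  graphics::legend("topleft", c("SOU", "F_red", "SOD"), lty = 1,
                   col = c("steelblue", "firebrick", "black"), bty = "n")
  invisible(ft)
}
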