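# Grid construction, bioturbation profile, diffusivities, DBL flux and the
# conservative finite-volume transport kernel.

p0 <- default_parameters()

test_that("stretched grid reproduces the reference resolutions", {
  # reference resolution: 500 cells, 0.4 cm surface scale
  g <- build_grid(500, 50, 0.4)
  expect_true(all(diff(g$x_int) > 0))
  expect_equal(g$x_int[length(g$x_int)], 50)
  dx <- diff(g$x_int)
  top_cm <- dx[g$x_int[-1] <= 1]
  expect_gte(min(top_cm), 0.004 * 0.9)
  expect_lte(max(top_cm), 0.013 * 1.1)
  expect_equal(dx[findInterval(30, g$x_int)], 0.29, tolerance = 0.1)
  expect_equal(dx[findInterval(49.9, g$x_int)], 0.48, tolerance = 0.1)
  # spacing grows monotonically with depth
  expect_true(all(diff(dx) > 0))
})

test_that("desk-scale grid resolves the interface and covers the column", {
  g <- build_grid(80)
  expect_equal(g$n, 80L)
  expect_lte(g$h[1], 0.02)
  expect_equal(max(g$x_int), 50)
  expect_error(build_grid(10), "at least 20")
  expect_error(build_grid(20, stretch = 60), "too coarse")
})

test_that("bioturbation profile follows the tanh attenuation law", {
  expect_equal(bioturbation_coefficient(0, 1, p0), 1 + p0$Db_min)
  expect_equal(bioturbation_coefficient(20, 1, p0), p0$Db_min,
               tolerance = 1e-6)
  # at x = H the numerator tanh vanishes
  expect_equal(bioturbation_coefficient(0.5, 1, p0),
               1 / (1 + tanh(0.5 / 1.43)) + 0.01, tolerance = 1e-6)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(bioturbation_coefficient(x, 1, p0)) <= 0))
})

test_that("tortuosity correction uses the natural logarithm", {
  expect_equal(effective_solute_diffusivity(1, 0.84), 1 / (1 - log(0.84^2)))
  expect_equal(effective_solute_diffusivity(380, 0.84) / 380, 0.7415,
               tolerance = 1e-3)
  expect_equal(effective_solute_diffusivity(100, 0.999999), 100,
               tolerance = 1e-4)
  expect_equal(effective_solute_diffusivity(0, 0.5), 0)
  expect_error(effective_solute_diffusivity(1, 1.2), "porosity")
  # factor in (0, 1] for any admissible porosity
  phis <- seq(0.05, 0.95, by = 0.1)
  fac <- effective_solute_diffusivity(1, phis)
  expect_true(all(fac > 0 & fac <= 1))
})

test_that("DBL flux is the linear film law with the right sign", {
  expect_equal(dbl_flux(400, 0.1, 0.1, 0.082), 0)
  expect_equal(dbl_flux(400, 0.1, 0, 0.082), 400 * 0.1 / 0.082,
               tolerance = 1e-9)
  # efflux (sediment concentration above bottom water) is negative
  expect_lt(dbl_flux(300, 0.05, 0.5, 0.082), 0)
  expect_error(dbl_flux(300, 1, 0, 0), "positive")
})

test_that("transport is discretely conservative", {
  g <- build_grid(40)
  set.seed(11)
  C <- matrix(abs(rnorm(g$n * 22, 1, 0.3)), g$n, 22,
              dimnames = list(NULL, colnames(stoichiometry_matrix(p0))))
  bc <- list(B = local_state(O2 = 0.1, NO3 = 0.05, SO4 = 0.1, NH4 = 0.2,
                             CH4 = 0.1, HCO3 = 1)[1:12],
             J = local_state(OM1 = 623, OM2 = 267, Mo1 = 10)[13:22])
  dC <- transport_tendency(C, g, p0, bc, v = 0.33, Db0 = 1)
  eps <- c(rep(p0$porosity, 12), rep(p0$rho_b * (1 - p0$porosity), 10))
  # total mass change equals boundary influx minus burial outflow, per species
  dM <- colSums(dC * g$h) * eps
  balance <- attr(dC, "flux_top") - attr(dC, "flux_bottom")
  expect_equal(unname(dM), unname(balance), tolerance = 1e-10)
})

test_that("uniform state with matched boundary has zero tendency", {
  g <- build_grid(30)
  C <- matrix(0.25, g$n, 22, dimnames = list(NULL, names(local_state())))
  bc <- list(B = rep(0.25, 12), J = rep(0, 10))
  names(bc$B) <- names(local_state())[1:12]
  names(bc$J) <- names(local_state())[13:22]
  dC <- transport_tendency(C, g, p0, bc, v = 0, Db0 = 0)
  # solutes: B = C everywhere, no advection -> nothing moves
  expect_lt(max(abs(dC[, 1:12])), 1e-12)
})

test_that("steady advective column matches the analytic concentration", {
  # pure burial of a solid with constant deposition: C* = J / (m v)
  p <- default_parameters(Db_min = 0)
  g <- build_grid(60)
  m <- p$rho_b * (1 - p$porosity)
  J <- 623; v <- 0.33
  Cstar <- J / (m * v)
  C <- matrix(0, g$n, 22, dimnames = list(NULL, names(local_state())))
  C[, "OM1"] <- Cstar
  bc <- list(B = stats::setNames(rep(0, 12), names(local_state())[1:12]),
             J = stats::setNames(c(J, rep(0, 9)),
                                 names(local_state())[13:22]))
  dC <- transport_tendency(C, g, p, bc, v = v, Db0 = 0)
  expect_lt(max(abs(dC[, "OM1"])), 1e-9 * Cstar)
})

test_that("an advected slug moves at the burial velocity", {
  # method-of-characteristics oracle: centre of mass of a passive solid
  # pulse advances by v * dt (plus upwind smearing, which conserves mass)
  p <- default_parameters(Db_min = 0)
  g <- build_grid(400, 50, 2)   # nearly uniform fine grid
  C0 <- matrix(0, g$n, 22, dimnames = list(NULL, names(local_state())))
  C0[, "OM2"] <- exp(-((g$x - 10) / 1)^2)   # inert pool as passive tracer
  bc <- list(B = stats::setNames(rep(0, 12), names(local_state())[1:12]),
             J = stats::setNames(rep(0, 10), names(local_state())[13:22]))
  v <- 0.33
  com <- function(C) sum(g$x * C[, "OM2"] * g$h) / sum(C[, "OM2"] * g$h)
  # explicit Euler with a CFL-safe step over 1 year
  C <- C0
  nstep <- 400
  for (i in seq_len(nstep))
    C <- C + (1 / nstep) * transport_tendency(C, g, p, bc, v = v, Db0 = 0)
  expect_equal(com(C) - com(C0), v, tolerance = 0.05)
})
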