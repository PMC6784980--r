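# Method-of-lines assembly, engine parity, determinism and spin-up.

p0 <- default_parameters()

test_that("compiled and reference R engines agree on the tendency", {
  cfg <- cfg_small()
  ctx <- sediagen:::.model_context(p0, cfg)
  set.seed(3)
  st <- matrix(abs(rnorm(ctx$g$n * 22, 1, 0.4)), ctx$g$n, 22)
  st <- sweep(st, 2, c(rep(0.1, 12), rep(100, 10)), "*")
  colnames(st) <- colnames(stoichiometry_matrix(p0))
  dR <- model_rhs(1995, st, "SQ", solver_config(n_nodes = 30, stretch = 0.3,
                                                engine = "R"), p0)
  dC <- model_rhs(1995, st, "SQ", cfg, p0)
  expect_equal(dC, dR, tolerance = 1e-12)
})

test_that("with reactions off the rhs reduces to pure transport", {
  p <- params_inert()
  cfg <- cfg_small()
  ctx <- sediagen:::.model_context(p, cfg)
  set.seed(4)
  st <- matrix(abs(rnorm(ctx$g$n * 22, 0.5, 0.1)), ctx$g$n, 22)
  colnames(st) <- colnames(stoichiometry_matrix(p))
  dy <- model_rhs(2000, st, "SQ", cfg, p)
  bc <- sediagen:::.boundary_fun("SQ")(2000)
  dtr <- transport_tendency(st, ctx$g, p, bc, v = bc$v, Db0 = bc$Db0)
  expect_equal(unname(dy), unname(unclass(dtr)[seq_along(dy)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("an oxic surface cell consumes O2 and releases NH4", {
  cfg <- cfg_small()
  ctx <- sediagen:::.model_context(p0, cfg)
  st <- matrix(0, ctx$g$n, 22,
               dimnames = list(NULL, colnames(stoichiometry_matrix(p0))))
  st[, "O2"] <- 0.1
  st[, "OM1"] <- 500
  src <- net_source_terms(st, p0)
  expect_lt(src[1, "O2"], 0)
  expect_gt(src[1, "NH4"], 0)
  expect_gt(src[1, "CO2"], 0)
})

test_that("runs are deterministic and scenarios share their history", {
  cfg <- cfg_small()
  t1 <- run_scenario("SQ", cfg, p0, end = 1900, cache = FALSE)
  t2 <- run_scenario("SQ", cfg, p0, end = 1900, cache = FALSE)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  # SQ and M trajectories coincide at the 2018 branch point
  tSQ <- traj_small()
  tM <- run_scenario("M", cfg_small(), p0, end = 2050)
  expect_equal(state_at(tSQ, 2018), state_at(tM, 2018), tolerance = 1e-12)
  expect_gt(flux_table(tSQ)[201, "F_red"], flux_table(tM)[201, "F_red"])
})

test_that("spin-up converges to a quasi-steady pre-industrial column", {
  tr <- traj_small()   # spin-up ran inside (cached)
  s <- spin_up("SQ", cfg_small(), p0)
  expect_lt(attr(s, "drift"), 0.02)
  # the pre-industrial SOU is far below the eutrophic-era SOU ceiling
  bc <- sediagen:::.boundary_fun("SQ")(1860)
  sou1860 <- dbl_flux(382, bc$B[["O2"]], s[1, "O2"], p0$d_dbl)
  expect_gt(sou1860, 0)
  # doubling the spin-up changes the 1860 state only marginally
  s2 <- spin_up("SQ", cfg_small(), p0, years = 700)
  sou2 <- dbl_flux(382, bc$B[["O2"]], s2[1, "O2"], p0$d_dbl)
  expect_equal(sou1860, sou2, tolerance = 0.01)
})

test_that("state extraction interpolates between snapshots", {
  tr <- traj_small()
  s1 <- state_at(tr, 2014)
  s2 <- state_at(tr, 2015)
  mid <- state_at(tr, 2014.5)
  expect_equal(mid, (s1 + s2) / 2, tolerance = 1e-12)
  expect_error(state_at(tr, 1700), "outside")
  pr <- profile_at(tr, "CH4", 2015)
  expect_named(pr, c("depth_cm", "value"))
  expect_equal(nrow(pr), tr$grid$n)
})
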