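# Reaction network: limitation cascade, primary mineralization
# stoichiometry, secondary redox rate laws, elemental conservation, and a
# zero-dimensional batch oracle.

p0 <- default_parameters()

test_that("limitation cascade reproduces the Monod/inhibition identities", {
  # oxic factor with abundant lower TEAs: 0.1/(0.1 + 1e-3), methanogenesis off
  f <- limitation_factors(local_state(O2 = 0.1, NO3 = 1, Mo1 = 1e3,
                                      Foh1 = 1e3, SO4 = 1), p0)
  expect_equal(f[, "oxic"][[1]], 0.1 / 0.101, tolerance = 1e-6)
  expect_lt(f[, "methanogenesis"][[1]], 1e-4)
  # pure methanogenesis limit
  f0 <- limitation_factors(local_state(), p0)
  expect_equal(as.vector(f0), c(0, 0, 0, 0, 0, 1))
  # half-saturation identity
  fh <- limitation_factors(local_state(O2 = p0$K_O2), p0)
  expect_equal(fh[, "oxic"][[1]], 0.5)
  # all factors in [0,1], partition sums to <= 1
  set.seed(42)
  for (i in 1:20) {
    s <- local_state()
    s[c("O2", "NO3", "SO4")] <- runif(3, 0, 0.3)
    s[c("Mo1", "Mo2", "Foh1", "Foh2")] <- runif(4, 0, 300)
    f <- limitation_factors(s, p0)
    expect_true(all(f >= 0 & f <= 1))
    expect_lte(sum(f), 1 + 1e-12)
  }
})

test_that("raising O2 strictly suppresses all anaerobic pathways", {
  s_lo <- local_state(O2 = 1e-4, NO3 = 0.05, Mo1 = 20, Foh1 = 100, SO4 = 0.05)
  s_hi <- s_lo; s_hi["O2"] <- 0.1
  f_lo <- limitation_factors(s_lo, p0)
  f_hi <- limitation_factors(s_hi, p0)
  expect_true(all(f_hi[, 2:6] < f_lo[, 2:6]))
})

test_that("primary mineralization splits carbon and nutrients correctly", {
  # pure methanogenesis: rate = k_deg_CH4 * OM1, C split 1:1 CH4:CO2,
  # N released as 8/106 per C
  r <- primary_mineralization(local_state(OM1 = 100), p0)
  expect_equal(r$pathways[, "methanogenesis"][[1]], 5.28, tolerance = 1e-6)
  expect_equal(r$CH4[[1]], 2.64, tolerance = 1e-6)
  expect_equal(r$CO2[[1]], 2.64, tolerance = 1e-6)
  expect_equal(r$NH4[[1]], 5.28 * 8 / 106, tolerance = 1e-6)
  expect_equal(r$HPO4[[1]], 5.28 * 0.5 / 106, tolerance = 1e-6)
  # no reactive OM -> nothing happens
  r0 <- primary_mineralization(local_state(O2 = 0.2), p0)
  expect_equal(sum(r0$pathways), 0)
  # N:C release ratio is the elemental ratio in every pathway mix
  s <- local_state(OM1 = 50, O2 = 0.05, NO3 = 0.01, SO4 = 0.05, Mo1 = 30)
  r2 <- primary_mineralization(local_state(OM1 = 50, O2 = 0.05), p0)
  expect_equal(r2$NH4[[1]] / r2$total_C[[1]], 8 / 106, tolerance = 1e-9)
  expect_error(primary_mineralization(local_state(OM1 = -1), p0), "OM1")
})

test_that("stoichiometry matrix conserves every tracked element", {
  S <- stoichiometry_matrix(p0)
  E <- element_composition(p0)
  resid <- S %*% E
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("net source terms vanish on an empty column and close carbon", {
  src0 <- net_source_terms(local_state(), p0)
  expect_lt(max(abs(src0)), 1e-6)
  # carbon closure on a common volume basis for a random active state
  set.seed(7)
  s <- local_state(O2 = 0.05, NO3 = 0.02, SO4 = 0.08, NH4 = 0.1, Mn2 = 0.03,
                   Fe2 = 0.04, HS = 0.01, CH4 = 0.6, CO2 = 0.2, HCO3 = 1.5,
                   HPO4 = 0.05, OM1 = 80, OM2 = 300, Mo1 = 20, Mo2 = 3,
                   Foh1 = 60, Foh2 = 10, FeS = 5, FeS2 = 1, Viv = 0.5,
                   MnCO3 = 10)
  src <- net_source_terms(s, p0)
  E <- element_composition(p0)
  m_phi <- p0$rho_b * (1 - p0$porosity) / p0$porosity
  basis <- c(rep(1, 12), rep(m_phi, 10))   # common porewater-volume basis
  for (el in colnames(E)) {
    tot <- sum(src[1, ] * basis * E[, el])
    scale_el <- sum(abs(src[1, ]) * basis * E[, el]) + 1e-12
    expect_lt(abs(tot) / scale_el, 1e-10)
  }
})

test_that("secondary rate laws reproduce hand-computed products", {
  # nitrification: k * NH4 * O2 = 500 * 0.1 * 0.1 = 5
  s <- local_state(NH4 = 0.1, O2 = 0.1)
  src <- net_source_terms(s, p0)
  expect_equal(unname(src[1, "NO3"]), 5, tolerance = 1e-3)
  expect_equal(unname(src[1, "NH4"]), -5, tolerance = 1e-3)
  expect_equal(unname(src[1, "O2"]), -10, tolerance = 1e-3)
  # anaerobic CH4 oxidation: 0.5 * 0.5 * 0.11 = 0.0275
  s2 <- local_state(CH4 = 0.5, SO4 = 0.11)
  src2 <- net_source_terms(s2, p0)
  expect_equal(unname(src2[1, "HS"]), 0.0275, tolerance = 1e-4)
  # pyrite formation in native solid units: 4 * 10 * 0.01 = 0.4 per yr
  s3 <- local_state(FeS = 10, HS = 0.01)
  src3 <- net_source_terms(s3, p0)
  expect_equal(unname(src3[1, "FeS2"]), 0.4, tolerance = 1e-3)
  # anoxia shuts down every aerobic oxidation
  s4 <- local_state(NH4 = 0.3, Mn2 = 0.1, Fe2 = 0.1, HS = 0.05, CH4 = 1)
  src4 <- net_source_terms(s4, p0)
  expect_lt(abs(src4[1, "NO3"]), 1e-6)   # no nitrification without O2
})

test_that("oxic mineralization consumes one O2 per carbon", {
  s <- local_state(OM1 = 100, O2 = 0.3)
  src <- net_source_terms(s, p0)
  r <- primary_mineralization(s, p0)
  m_phi <- p0$rho_b * (1 - p0$porosity) / p0$porosity
  totC_pw <- r$total_C[[1]] * m_phi
  expect_equal(unname(src[1, "O2"] / totC_pw), -1, tolerance = 1e-3)
  expect_equal(unname(src[1, "CO2"] / totC_pw), 1, tolerance = 1e-3)
})

test_that("closed-box decay is monotone with terminal 1:1 CH4:CO2 split", {
  # batch reactor: OM1 only, no TEAs -> pure methanogenesis
  y0 <- local_state(OM1 = 100)
  f <- function(t, y, parms) {
    names(y) <- names(y0)
    list(as.vector(net_source_terms(y, p0)))
  }
  out <- deSolve::ode(y = y0, times = seq(0, 40, 5), func = f, parms = NULL,
                      method = "lsoda")
  om1 <- out[, "OM1"]
  expect_true(all(diff(om1) < 0))
  # decay no faster than the fastest rate constant
  expect_gt(min(om1), 100 * exp(-max(p0$k_deg_O2) * 40) - 1)
  # terminal split: accumulated CH4 == accumulated CO2 (porewater basis)
  expect_equal(unname(out[nrow(out), "CH4"]), unname(out[nrow(out), "CO2"]),
               tolerance = 1e-3)
  # effective decay constant matches k_deg_CH4
  k_eff <- -log(om1[length(om1)] / om1[1]) / 40
  expect_equal(k_eff, p0$k_deg_CH4, tolerance = 0.05)
})

test_that("stoichiometry table export is audit-ready", {
  f <- tempfile(fileext = ".tsv")
  write_stoichiometry(f, p0)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), nrow(stoichiometry_matrix(p0)))
  expect_true(all(c("reaction", "O2", "OM1", "FeS2") %in% names(tab)))
  unlink(f)
})
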